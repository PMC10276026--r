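trait,rl_aa,d2
NBP,0.30,0.20
FWB,0.32,0.27
RL,0.71,0.08
NRB,0.69,0.15
WF,0.65,0.20
WS,0.80,0.11
AP,0.60,0.17
PY,0.86,0.04
EDF,0.69,0.14
LDF,0.75,0.10
EDS,0.77,0.10
LDS,1.00,0.00
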