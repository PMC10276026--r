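trait,model,sigma2_a,sigma2_d,sigma2_e,h2,H2
NBP,BLUP,0.65,NA,1.12,0.37,NA
NBP,GBLUP-A,0.64,NA,1.16,0.35,NA
NBP,GBLUP-AD,0.19,0.33,1.13,0.12,0.31
FWB,BLUP,1.3,NA,1.27,0.51,NA
FWB,GBLUP-A,1.24,NA,1.31,0.49,NA
FWB,GBLUP-AD,0.39,0.62,1.27,0.17,0.44
RL,BLUP,59.61,NA,126.49,0.32,NA
RL,GBLUP-A,50.39,NA,129.3,0.28,NA
RL,GBLUP-AD,35.74,13.7,126.18,0.20,0.28
NRB,BLUP,357.05,NA,151.17,0.70,NA
NRB,GBLUP-A,357.7,NA,153.88,0.70,NA
NRB,GBLUP-AD,248.48,72.26,152.11,0.53,0.68
WF,BLUP,54.65,NA,9.17,0.86,NA
WF,GBLUP-A,55.45,NA,9.22,0.86,NA
WF,GBLUP-AD,36.32,11.42,9.20,0.64,0.84
WS,BLUP,30.06,NA,6.59,0.82,NA
WS,GBLUP-A,29.00,NA,6.61,0.81,NA
WS,GBLUP-AD,23.17,3.55,6.61,0.70,0.80
AP,BLUP,7.07,NA,3.97,0.64,NA
AP,GBLUP-A,6.8,NA,4.00,0.63,NA
AP,GBLUP-AD,4.08,1.67,3.99,0.42,0.59
PY,BLUP,17.36,NA,17.85,0.49,NA
PY,GBLUP-A,15.26,NA,17.87,0.46,NA
PY,GBLUP-AD,13.13,1.35,17.86,0.41,0.45
EDF,BLUP,0.91,NA,0.47,0.66,NA
EDF,GBLUP-A,0.92,NA,0.48,0.66,NA
EDF,GBLUP-AD,0.63,0.18,0.48,0.49,0.63
LDF,BLUP,0.82,NA,0.59,0.58,NA
LDF,GBLUP-A,0.81,NA,0.6,0.58,NA
LDF,GBLUP-AD,0.61,0.13,0.6,0.46,0.55
EDS,BLUP,0.88,NA,0.41,0.68,NA
EDS,GBLUP-A,0.88,NA,0.41,0.68,NA
EDS,GBLUP-AD,0.68,0.12,0.41,0.56,0.66
LDS,BLUP,0.7,NA,0.45,0.61,NA
LDS,GBLUP-A,0.63,NA,0.45,0.58,NA
LDS,GBLUP-AD,0.63,0,0.45,0.58,0.58
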