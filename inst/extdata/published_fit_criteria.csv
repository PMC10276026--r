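trait,model,pev,r,ll,aic,bic,k_fixed
NBP,BLUP,0.21,0.82,-345.05,698.1,717.82,4
NBP,GBLUP-A,0.19,0.83,-348.71,705.42,725.14,4
NBP,GBLUP-AD,0.15,0.84,-340.83,689.67,709.39,4
FWB,BLUP,0.39,0.83,-257.97,521.93,535.38,3
FWB,GBLUP-A,0.36,0.84,-254.04,514.08,527.52,3
FWB,GBLUP-AD,0.30,0.84,-249.55,505.1,518.55,3
RL,BLUP,28.67,0.72,-299.72,605.44,618.89,3
RL,GBLUP-A,24.28,0.72,-291.64,589.28,602.73,3
RL,GBLUP-AD,22.64,0.74,-290.89,587.78,601.23,3
NRB,BLUP,57.62,0.92,-181.88,369.77,383.21,3
NRB,GBLUP-A,53.98,0.92,-171.95,349.9,363.35,3
NRB,GBLUP-AD,91.02,0.85,-170.75,347.5,360.94,3
WF,BLUP,1.25,0.99,599.6,-1193.19,-1175.66,3
WF,GBLUP-A,1.05,0.99,613.54,-1221.08,-1203.55,3
WF,GBLUP-AD,10.36,0.88,616.67,-1227.34,-1209.81,3
WS,BLUP,0.87,0.99,422.77,-839.54,-822.05,3
WS,GBLUP-A,0.75,0.99,443.65,-881.3,-863.81,3
WS,GBLUP-AD,4.16,0.92,444.53,-883.06,-865.57,3
AP,BLUP,0.47,0.97,-302.46,610.93,628.41,3
AP,GBLUP-A,0.43,0.97,-287.92,581.84,599.32,3
AP,GBLUP-AD,1.5,0.86,-283.82,573.64,591.12,3
PY,BLUP,1.94,0.94,-467.05,940.1,957.58,3
PY,GBLUP-A,1.76,0.94,-437.3,880.6,898.08,3
PY,GBLUP-AD,2.81,0.90,-436.97,879.94,897.42,3
EDF,BLUP,0.06,0.97,-285.78,577.56,595.05,3
EDF,GBLUP-A,0.06,0.97,-273.44,552.88,570.37,3
EDF,GBLUP-AD,0.19,0.88,-271.87,549.75,567.24,3
LDF,BLUP,0.07,0.95,-262.42,530.85,548.34,3
LDF,GBLUP-A,0.07,0.96,-247.17,500.34,517.84,3
LDF,GBLUP-AD,0.16,0.88,-245.88,497.77,515.26,3
EDS,BLUP,0.06,0.97,-50.26,106.52,123.9,3
EDS,GBLUP-A,0.05,0.97,-35.53,77.06,94.44,3
EDS,GBLUP-AD,0.16,0.90,-34.56,75.11,92.49,3
LDS,BLUP,0.06,0.96,27.91,-49.82,-32.43,3
LDS,GBLUP-A,0.05,0.96,57.36,-108.72,-91.33,3
LDS,GBLUP-AD,0.05,0.96,57.36,-108.72,-91.33,3
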