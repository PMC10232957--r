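trait,mean,gcv,pcv,h2bs,ga,gam,sed
AGP,59.80,50.00,55.20,82.04,50.54,84.51,8.08
AVI,1953.26,71.06,76.20,86.96,2486.37,127.29,310.35
SL,22.78,36.73,40.49,82.29,14.18,62.26,2.24
RL,6.86,40.95,46.09,78.95,4.57,66.60,0.84
RI,3.05,30.75,33.28,85.37,16.49,540.89,2.24
SRR,3.85,34.26,80.23,18.23,0.49,12.87,1.61
NOL,1.88,18.58,25.64,52.49,0.38,20.08,0.19
NOR,6.20,36.12,41.29,76.52,3.53,56.93,0.72
FW,0.15,46.55,83.50,31.08,0.04,29.80,0.06
DW,0.09,60.86,88.15,47.67,0.05,59.77,0.03
KL,6.61,16.19,16.43,97.19,2.14,32.42,0.15
KB,2.41,18.20,18.39,97.86,0.88,36.68,0.05
LBR,2.79,15.14,15.38,96.95,0.84,30.24,0.06
HSW,2.36,27.53,27.69,98.85,1.32,56.05,0.06
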