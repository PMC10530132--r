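trial,X1,X2,X3,X4,X5,X6,X7,X8,X9,X10,dcw_mean,dcw_sd
1,1,1,0.5,0,0,0.25,0.5,1,2,0,0.50,0.23
2,1,2,0.25,0.5,0,0.25,0.25,1,2,0.5,2.35,0.07
3,0,2,0.5,0,2,0.25,0.25,0,2,0.5,1.64,0.91
4,1,1,0.5,0.5,0,0.5,0.25,0,1,0.5,2.25,0.19
5,1,2,0.25,0.5,2,0.25,0.5,0,1,0,2.48,0.31
6,1,2,0.5,0,2,0.5,0.25,1,1,0,2.81,0.18
7,0,2,0.5,0.5,0,0.5,0.5,0,2,0,1.19,1.01
8,0,1,0.5,0.5,2,0.25,0.5,1,1,0.5,4.12,0.30
9,0,1,0.25,0.5,2,0.5,0.25,1,2,0,3.73,1.28
10,1,1,0.25,0,2,0.5,0.5,0,2,0.5,0.58,0.30
11,0,2,0.25,0,0,0.5,0.5,1,1,0.5,1.77,0.38
12,0,1,0.25,0,0,0.25,0.25,0,1,0,0.94,0.19
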