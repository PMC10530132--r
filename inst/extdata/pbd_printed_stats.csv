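statistic,X1,X2,X3,X4,X5,X6,X7,X8,X9,X10,X11
effect,-0.401,0.021,0.111,1.313,1.06,0.049,-0.514,1.031,-0.729,0.176,0.062
ss,0.483,0.001,0.037,5.173,3.37,0.007,0.791,3.19,1.593,0.093,0.012
ms,0.483,0.001,0.037,5.173,3.37,0.007,0.791,3.19,1.593,0.093,0.012
f,41.95,0.11,3.2,449.6,292.9,0.63,68.78,277.3,138.5,8.11,1
p,0.098,0.793,0.325,0.030,0.037,0.573,0.076,0.038,0.054,0.215,0.5
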