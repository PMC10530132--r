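factor,level_1,level_2,level_3,ss,contribution
A,0.85,4.69,3.16,22.38,30
B,0.30,3.89,4.51,30.97,41
C,0.93,3.71,4.06,17.63,23
D,2.10,2.86,3.75,4.09,5
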