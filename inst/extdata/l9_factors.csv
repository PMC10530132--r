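symbol,name,units,level_1,level_2,level_3
A,Olive oil,mL,0,2,4
B,CaCO3,g,0,0.25,0.5
C,Yeast extract,g,0.25,0.5,0.75
D,Soy powder,g,0,0.25,0.5
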