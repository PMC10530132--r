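symbol,name,units,level_plus,level_minus
X1,Lignin,mL,1,0
X2,Inoculation,pieces,2,1
X3,Yeast extract,g,0.5,0.25
X4,CaCO3,g,0.5,0
X5,Olive oil,mL,2,0
X6,Yolk powder,g,0.5,0.25
X7,Soy powder,g,0.5,0.25
X8,Tween 80,mL,1,0
X9,KH2PO4,g,2,1
X10,Mung bean powder,g,0.5,0
X11,Dummy,,NA,NA
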