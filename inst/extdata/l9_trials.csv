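trial,olive_oil,caco3,ye,soy,biomass_mean,biomass_sd,sn
L1,0.0,0.0,0.3,0.0,0.65,0.16,-4.52
L2,0.0,0.3,0.5,0.3,1.36,0.09,2.61
L3,0.0,0.5,0.8,0.5,1.71,0.22,4.47
L4,2.0,0.0,0.5,0.5,1.61,0.28,3.75
L5,2.0,0.3,0.8,0.0,2.11,0.37,6.03
L6,2.0,0.5,0.3,0.3,1.66,0.14,4.29
L7,4.0,0.0,0.8,0.3,1.27,0.21,1.68
L8,4.0,0.3,0.3,0.5,1.52,0.31,3.03
L9,4.0,0.5,0.5,0.0,1.81,0.29,4.78
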