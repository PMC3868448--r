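lineage,assay,mu_dct,sd_dct
Rock,1,-0.4,0.09
Rock,2,0,0.11
Rock,3,-0.7,0.07
EE,1,-2.7,0.03
EE,2,-2.4,0.04
EE,3,-3.0,0.04
Hyb,1,-2.0,0.07
Hyb,2,-1.7,0.05
Hyb,3,-2.4,0.06
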