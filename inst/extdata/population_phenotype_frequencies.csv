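locality,status,n,freq_IleIle_ValVal,freq_IleIle_ValIle,freq_IleIle_IleIle,freq_IleMet_ValVal,freq_IleMet_ValIle,freq_MetMet_ValVal
Aparecida de Goiania,R,18,0.056,0,0.222,0.500,0.222,0
Aparecida de Goiania,S,19,0.105,0.053,0,0.842,0,0
Campo Grande,R,22,0.045,0.273,0.455,0.091,0.136,0
Campo Grande,S,17,0.118,0.118,0,0.588,0.176,0
Cuiaba,R,13,0.231,0,0.385,0.308,0.077,0
Cuiaba,S,14,0.571,0.143,0,0.286,0,0
Dourados,R,16,0,0.063,0.500,0.313,0.125,0
Dourados,S,20,0.250,0.250,0.100,0.350,0.050,0
Fortaleza,R,16,0.250,,,0.750,,0
Fortaleza,S,16,0.313,,,0.688,,0
Maceio,R,15,0.467,,,0.533,,0
Maceio,S,15,0.333,,,0.667,,0
Uberaba,R,23,0.043,0.087,0.391,0.174,0.304,0
Uberaba,S,20,0.300,0.050,0.050,0.400,0.200,0
Boa Vista,unclassified,20,0.950,0,0.050,,,
Cachoeiro do Itapemirim,unclassified,20,0.200,0,0.250,0.200,0.350,0
Colatina,unclassified,16,0,0.250,0.063,0.625,0.063,0
Foz do Iguacu,unclassified,19,0,0.053,0.526,0.053,0.368,0
Ijui,unclassified,20,0.900,,,0.100,,0
Macapa,unclassified,20,0.300,,,0.700,,0
Santa Barbara,unclassified,16,0.938,,,0.063,,0
Santa Rosa,unclassified,20,0.650,,,0.350,,0
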