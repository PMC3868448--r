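specimen,site1011,intron,site1016
UBR-04,Ile,A,Val
UBR-04,Ile,B,Val
UBR-08,Met,A,Val
UBR-08,Ile,B,Val
UBR-10,Met,A,Val
UBR-10,Ile,A,Ile
UBR-10,Ile,B,Val
UBR-S25,Ile,A,Val
UBR-S25,Ile,A,Ile
UBR-S26,Ile,A,Val
UBR-S26,Ile,A,Ile
UBR-R1,Ile,A,Ile
UBR-R3,Ile,A,Ile
UBR-R10,Ile,B,Val
UBR-R11,Ile,A,Ile
UBR-R11,Ile,B,Val
UBR-R13,Met,A,Val
UBR-R13,Ile,A,Ile
UBR-R13,Ile,B,Val
UBR-R20,Ile,A,Ile
UBR-R22,Ile,A,Ile
UBR-R26,Ile,A,Ile
CUI-01,Ile,A,Ile
CUI-01,Ile,B,Val
CUI-02,Ile,A,Val
CUI-03,Ile,A,Val
CUI-03,Ile,B,Val
CUI-04,Ile,A,Val
CUI-04,Ile,B,Val
CUI-07,Ile,A,Val
CUI-07,Ile,B,Val
CUI-08,Ile,A,Val
CUI-08,Ile,B,Val
CUI-12,Ile,A,Val
CUI-12,Ile,B,Val
CUI-R16,Ile,A,Val
CUI-R16,Ile,B,Val
CUI-S15,Met,A,Val
CUI-S15,Ile,B,Val
APG-01,Ile,A,Val
APG-01,Ile,A,Ile
APG-02,Met,A,Val
APG-02,Ile,A,Ile
APG-02,Ile,B,Val
APG-04,Met,A,Val
APG-04,Ile,B,Val
APG-05,Met,A,Val
APG-05,Ile,B,Val
APG-06,Met,A,Val
APG-06,Ile,B,Val
APG-07,Met,A,Val
APG-07,Ile,A,Ile
APG-07,Ile,B,Val
APG-08,Met,A,Val
APG-08,Ile,B,Val
APG-09,Met,A,Val
APG-09,Ile,B,Val
APG-10,Met,A,Val
APG-10,Ile,B,Val
APG-11,Met,A,Val
APG-11,Ile,B,Val
APG-12,Met,A,Val
APG-12,Ile,B,Val
COM-02,Met,A,Val
COM-02,Ile,B,Val
COM-07,Ile,B,Val
COM-09,Ile,B,Val
hrjg-21,Met,A,Val
hrjg-21,Ile,B,Val
hrjg-22,Ile,A,Val
hrjg-23,Ile,B,Val
hrjg-28,Ile,A,Val
hrjg-28,Ile,B,Val
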