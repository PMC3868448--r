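cross_id,parent1_phenotype,parent2_phenotype,n_IleIle,n_IleMet,n_MetMet,generation
1,Ile/Met,Ile/Ile,0,20,0,F1
2,Ile/Met,Ile/Ile,0,20,0,F1
3,Ile/Met,Ile/Ile,8,12,0,F1
4,Ile/Ile,Ile/Met,9,9,0,F1
5,Ile/Ile,Ile/Met,0,30,0,F1
6,Ile/Met,Ile/Ile,0,30,0,F1
7,Ile/Met,Ile/Ile,0,22,0,F1
1.1,Ile/Met,Ile/Met,5,25,0,F2
2.1,Ile/Met,Ile/Met,7,23,0,F2
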