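ligand_conc,ligand_unit,norm_rate_pct,rate_sd,end,A0_uM,seeds_nM
0,nM,102.742,2,barbed,2,2
13.636363636363635,nM,52.986,2,barbed,2,2
27.27272727272727,nM,37.308,2,barbed,2,2
40.90909090909091,nM,28.809,2,barbed,2,2
54.54545454545454,nM,22.872,2,barbed,2,2
68.18181818181817,nM,18.181,2,barbed,2,2
81.81818181818181,nM,18.79,2,barbed,2,2
95.45454545454544,nM,13.606,2,barbed,2,2
109.09090909090908,nM,16.298,2,barbed,2,2
122.72727272727272,nM,10.908,2,barbed,2,2
136.36363636363635,nM,12.639,2,barbed,2,2
150,nM,13.765,2,barbed,2,2
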