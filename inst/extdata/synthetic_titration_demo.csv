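ligand_conc_uM,signal,signal_sd
0,100.54838337885867,0.4
0.14285714285714285,101.6114431516828,0.4
0.2857142857142857,103.80543899842895,0.4
0.42857142857142855,105.71685296585619,0.4
0.5714285714285714,107.40243032517661,0.4
0.7142857142857142,108.93805013612996,0.4
0.8571428571428571,111.27127546564225,0.4
1,112.23632075838215,0.4
1.1428571428571428,114.57333465620326,0.4
1.2857142857142856,115.06747482521229,0.4
1.4285714285714284,116.72481356779423,0.4
1.5714285714285714,117.98403997310733,0.4
1.7142857142857142,117.15202431836776,0.4
1.857142857142857,118.0529701820512,0.4
2,118.43861323335587,0.4
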