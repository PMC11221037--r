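energy_mev,csda_g_cm2
0.01,0.0002515
0.02,0.0008566
0.03,0.001756
0.05,0.00432
0.07,0.00783
0.1,0.01431
0.15,0.02817
0.2,0.04487
0.3,0.08421
0.4,0.128
0.5,0.1766
0.7,0.2752
1,0.4367
1.5,0.7075
2,0.9785
3,1.514
4,2.037
5,2.55
7,3.545
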