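# I
0.350,0.028,0.000,0.000,0.000,0.000,0.000
0.0280000000000,0.3500000000000,0.0211660104885,0.0000000000000,0.0000000000000,0.0000000000000,0.0000000000000
0.0000000000000,0.0211660104885,0.2000000000000,0.0101192885125,0.0000000000000,0.0000000000000,0.0000000000000
0.0000000000000,0.0000000000000,0.0101192885125,0.0800000000000,0.0016000000000,0.0000000000000,0.0000000000000
0.0000000000000,0.0000000000000,0.0000000000000,0.0016000000000,0.0050000000000,0.0003577708764,0.0000000000000
0.000000000000000,0.000000000000000,0.000000000000000,0.000000000000000,0.000357770876400,0.004000000000000,0.000277128129211
0.000000000000000,0.000000000000000,0.000000000000000,0.000000000000000,0.000000000000000,0.000277128129211,0.003000000000000
# D
1.200,0.096,0.000,0.000,0.000,0.000,0.000
0.0960000000000,1.2000000000000,0.0783836717691,0.0000000000000,0.0000000000000,0.0000000000000,0.0000000000000
0.0000000000000,0.0783836717691,0.8000000000000,0.0554256258422,0.0000000000000,0.0000000000000,0.0000000000000
0.0000000000000,0.0000000000000,0.0554256258422,0.6000000000000,0.0195959179423,0.0000000000000,0.0000000000000
0.0000000000000,0.0000000000000,0.0000000000000,0.0195959179423,0.1000000000000,0.0071554175280,0.0000000000000
0.000000000000,0.000000000000,0.000000000000,0.000000000000,0.007155417528,0.080000000000,0.006400000000
0.0000,0.0000,0.0000,0.0000,0.0000,0.0064,0.0800
# K
10.0, 0.8, 0.0, 0.0, 0.0, 0.0, 0.0
 0.800000000000,10.000000000000, 0.619677335393, 0.000000000000, 0.000000000000, 0.000000000000, 0.000000000000
0.000000000000,0.619677335393,6.000000000000,0.438178046004,0.000000000000,0.000000000000,0.000000000000
0.000000000000,0.000000000000,0.438178046004,5.000000000000,0.195959179423,0.000000000000,0.000000000000
0.0000000000000,0.0000000000000,0.0000000000000,0.1959591794227,1.2000000000000,0.0876356092008,0.0000000000000
0.0000000000000,0.0000000000000,0.0000000000000,0.0000000000000,0.0876356092008,1.0000000000000,0.0715541752800
0.00000000000,0.00000000000,0.00000000000,0.00000000000,0.00000000000,0.07155417528,0.80000000000
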