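energy_keV,mass_atten_cm2_g
5.0000,680.49
5.3791,563.52
5.7870,466.17
6.2259,385.17
6.6980,317.87
7.2059,262.11
7.7523,215.97
8.3401,177.84
8.9726,146.34
9.6530,120.28
10.3849,98.825
11.1724,81.175
12.0196,66.665
12.9311,54.74
13.9116,44.925
14.9665,36.86
16.1014,30.238
17.3224,24.812
18.6359,20.366
20.0491,16.723
21.5694,13.737
22.9050,11.691
23.0550,11.488
23.1450,11.369
23.2050,11.29
23.2195,11.271
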