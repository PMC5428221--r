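energy_keV,mass_atten_cm2_g
5.0000,529.27
5.3278,448.03
5.6771,378.98
6.0492,320.39
6.4458,270.72
6.8684,228.63
7.3187,193
7.7985,162.84
8.3097,137.34
8.8545,115.79
9.4350,97.542
10.0535,82.155
10.7126,69.166
11.4149,58.204
12.1633,48.97
12.9607,41.199
13.8103,34.666
14.7157,29.174
15.6805,24.557
16.7084,20.675
17.8038,17.412
18.6710,15.312
18.8210,14.985
18.9110,14.794
18.9710,14.668
18.9855,14.638
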