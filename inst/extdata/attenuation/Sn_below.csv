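energy_keV,mass_atten_cm2_g
5.0000,871.93
5.4382,705.17
5.9148,569.05
6.4332,458.45
6.9970,368.84
7.6102,296.34
8.2772,237.77
9.0026,190.52
9.7916,152.39
10.6497,121.83
11.5830,97.358
12.5982,77.771
13.7023,62.101
14.9031,49.569
16.2093,39.557
17.6298,31.56
19.1749,25.173
20.8554,20.078
22.6832,16.02
24.6711,12.79
26.8333,10.216
28.8850,8.3721
29.0350,8.2562
29.1250,8.1877
29.1850,8.1425
29.1995,8.1316
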