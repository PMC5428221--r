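energy_keV,mass_atten_cm2_g
5.0000,714.77
5.3913,588.84
5.8133,484.53
6.2683,398.26
6.7589,326.93
7.2879,268.09
7.8583,219.66
8.4734,179.85
9.1366,147.12
9.8517,120.23
10.6228,98.213
11.4542,80.2
12.3507,65.477
13.3173,53.448
14.3597,43.614
15.4836,35.575
16.6954,29.012
18.0022,23.665
19.4111,19.31
20.9304,15.763
22.5686,12.873
24.0350,10.874
24.1850,10.694
24.2750,10.588
24.3350,10.519
24.3495,10.502
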