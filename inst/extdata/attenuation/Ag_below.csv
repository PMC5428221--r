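energy_keV,mass_atten_cm2_g
5.0000,763.97
5.4034,626.19
5.8393,512.62
6.3104,419.15
6.8195,342.32
7.3697,279.21
7.9642,227.52
8.6067,185.26
9.3011,150.66
10.0515,122.42
10.8624,99.442
11.7387,80.739
12.6857,65.536
13.7092,53.186
14.8152,43.154
16.0104,34.999
17.3020,28.379
18.6979,23.015
20.2064,18.671
21.8365,15.153
23.5982,12.305
25.2020,10.319
25.3520,10.157
25.4420,10.061
25.5020,9.9979
25.5165,9.9827
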