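energy_keV,mass_atten_cm2_g
5.0000,561.89
5.3410,472.93
5.7053,397.69
6.0944,334.16
6.5101,280.61
6.9541,235.52
7.4284,197.57
7.9350,165.64
8.4762,138.82
9.0543,116.27
9.6719,97.308
10.3315,81.428
11.0362,68.126
11.7889,56.965
12.5929,47.623
13.4518,39.804
14.3693,33.273
15.3493,27.819
16.3962,23.264
17.5144,19.459
18.7090,16.282
19.6850,14.195
19.8350,13.907
19.9250,13.739
19.9850,13.628
19.9995,13.601
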