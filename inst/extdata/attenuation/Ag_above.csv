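energy_keV,mass_atten_cm2_g
25.5175,56.827
25.5320,56.728
25.5920,56.323
25.6820,55.73
25.8320,54.783
26.4197,51.519
27.3382,47.227
28.2887,43.211
29.2722,39.527
30.2899,36.147
31.3430,33.049
32.4327,30.209
33.5603,27.602
34.7271,25.211
35.9345,23.022
37.1838,21.019
38.4766,19.188
39.8143,17.513
41.1986,15.982
42.6309,14.582
44.1131,13.303
45.6468,12.135
47.2338,11.068
48.8760,10.093
50.5752,9.2032
52.3336,8.3881
54.1531,7.6441
56.0358,6.9661
57.9841,6.3484
60.0000,5.7856
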