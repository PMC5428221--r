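energy_keV,mass_atten_cm2_g
17.9985,97.674
18.0130,97.442
18.0730,96.492
18.1630,95.093
18.3130,92.834
18.9012,84.779
19.8331,74.877
20.8110,66.084
21.8372,58.283
22.9139,51.366
24.0437,45.234
25.2292,39.809
26.4732,35.016
27.7785,30.772
29.1482,27.03
30.5854,23.735
32.0935,20.835
33.6760,18.283
35.3364,16.038
37.0788,14.057
38.9070,12.314
40.8254,10.786
42.8384,9.4469
44.9506,8.2735
47.1670,7.2458
49.4927,6.3459
51.9330,5.5581
54.4937,4.8688
57.1806,4.2658
60.0000,3.7383
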