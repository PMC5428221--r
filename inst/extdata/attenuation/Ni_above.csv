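energy_keV,mass_atten_cm2_g
8.3335,341.33
8.3480,339.39
8.4080,331.51
8.4980,320.66
8.6480,304.85
9.0333,273.04
9.7748,222.5
10.5772,180.99
11.4455,146.9
12.3850,119.03
13.4017,96.302
14.5018,77.805
15.6922,62.771
16.9804,50.56
18.3743,40.649
19.8826,32.649
21.5147,26.199
23.2808,21.005
25.1919,16.828
27.2599,13.471
29.4976,10.775
31.9190,8.6183
34.5392,6.8941
37.3744,5.5122
40.4425,4.4069
43.7623,3.5281
47.3547,2.8298
51.2420,2.2749
55.4483,1.8341
60.0000,1.4839
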