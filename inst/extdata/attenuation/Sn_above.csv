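energy_keV,mass_atten_cm2_g
29.2005,44.637
29.2150,44.578
29.2750,44.333
29.3650,43.97
29.5150,43.373
30.0682,41.272
30.9464,38.252
31.8501,35.498
32.7803,32.936
33.7377,30.555
34.7230,28.341
35.7370,26.283
36.7807,24.37
37.8549,22.593
38.9605,20.939
40.0983,19.403
41.2694,17.977
42.4746,16.654
43.7151,15.427
44.9918,14.288
46.3058,13.232
47.6581,12.253
49.0499,11.346
50.4824,10.504
51.9568,9.7243
53.4742,9.0016
55.0359,8.332
56.6432,7.7117
58.2974,7.1371
60.0000,6.6033
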