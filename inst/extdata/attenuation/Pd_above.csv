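energy_keV,mass_atten_cm2_g
24.3505,60.546
24.3650,60.445
24.4250,60.029
24.5150,59.415
24.6650,58.416
25.2593,54.744
26.1865,49.858
27.1477,45.413
28.1441,41.325
29.1772,37.594
30.2481,34.192
31.3584,31.091
32.5094,28.259
33.7027,25.679
34.9398,23.329
36.2223,21.19
37.5518,19.244
38.9302,17.473
40.3591,15.862
41.8405,14.398
43.3763,13.066
44.9685,11.856
46.6191,10.756
48.3302,9.7569
50.1042,8.846
51.9433,8.019
53.8499,7.2692
55.8265,6.5896
57.8756,5.9736
60.0000,5.4155
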