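energy_keV,mass_atten_cm2_g
23.2205,65.903
23.2350,65.786
23.2950,65.307
23.3850,64.598
23.5350,63.445
24.1337,59.176
25.0671,53.584
26.0366,48.569
27.0436,44
28.0895,39.839
29.1759,36.059
30.3044,32.626
31.4764,29.5
32.6938,26.667
33.9583,24.101
35.2717,21.776
36.6359,19.672
38.0528,17.767
39.5246,16.044
41.0533,14.485
42.6411,13.075
44.2903,11.8
46.0033,10.648
47.7825,9.6031
49.6306,8.6588
51.5501,7.8072
53.5439,7.0392
55.6148,6.3469
57.7658,5.7229
60.0000,5.1606
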