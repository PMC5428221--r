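energy_keV,mass_atten_cm2_g
18.9865,90.474
19.0010,90.276
19.0610,89.463
19.1510,88.265
19.3010,86.323
19.8953,79.248
20.8318,70.336
21.8123,62.407
22.8390,55.341
23.9140,49.048
25.0395,43.446
26.2181,38.463
27.4522,34.023
28.7443,30.076
30.0972,26.578
31.5138,23.48
32.9971,20.736
34.5503,18.307
36.1765,16.159
37.8792,14.259
39.6622,12.568
41.5290,11.076
43.4837,9.7599
45.5304,8.6001
47.6734,7.578
49.9173,6.6775
52.2668,5.8843
54.7270,5.1859
57.3029,4.571
60.0000,4.0298
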