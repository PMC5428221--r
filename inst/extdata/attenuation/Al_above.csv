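energy_keV,mass_atten_cm2_g
5.0000,190.1
5.4473,149.09
5.9347,116.76
6.4656,91.301
7.0441,71.274
7.6742,55.563
8.3608,43.274
9.1088,33.653
9.9237,26.114
10.8116,20.257
11.7788,15.711
12.8326,12.185
13.9807,9.4525
15.2314,7.3365
16.5941,5.6992
18.0787,4.4331
19.6961,3.4549
21.4582,2.6995
23.3780,2.1166
25.4695,1.667
27.7481,1.3202
30.2306,1.0529
32.9351,0.84699
35.8816,0.68834
39.0918,0.56602
42.5891,0.47162
46.3993,0.39866
50.5504,0.34214
55.0729,0.29823
60.0000,0.26396
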