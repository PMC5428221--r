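energy_keV,mass_atten_cm2_g
20.0005,82.865
20.0150,82.694
20.0750,81.991
20.1650,80.953
20.3150,79.269
20.9135,73.061
21.8524,65.174
22.8334,58.148
23.8585,51.852
24.9296,46.214
26.0487,41.169
27.2181,36.645
28.4400,32.595
29.7168,28.983
31.0509,25.763
32.4448,22.895
33.9014,20.339
35.4233,18.064
37.0136,16.04
38.6752,14.238
40.4115,12.634
42.2257,11.204
44.1213,9.934
46.1021,8.8074
48.1717,7.8081
50.3343,6.922
52.5939,6.1365
54.9550,5.4403
57.4221,4.8235
60.0000,4.2771
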