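energy_keV,mass_atten_cm2_g
5.0000,489.4
5.3142,416.83
5.6482,354.83
6.0032,301.9
6.3805,256.75
6.7815,218.24
7.2077,185.43
7.6607,157.5
8.1421,133.72
8.6539,113.49
9.1977,96.271
9.7758,81.624
10.3902,69.164
11.0432,58.598
11.7372,49.631
12.4749,42.041
13.2589,35.617
14.0922,30.178
14.9778,25.575
15.9192,21.678
16.9196,18.379
17.6830,16.311
17.8330,15.943
17.9230,15.727
17.9830,15.586
17.9975,15.552
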