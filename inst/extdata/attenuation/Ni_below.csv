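energy_keV,mass_atten_cm2_g
5.0000,181.26
5.1227,169.74
5.2483,158.94
5.3771,148.82
5.5090,139.34
5.6442,130.46
5.7826,122.15
5.9245,114.36
6.0699,107.06
6.2188,100.23
6.3713,93.831
6.5277,87.839
6.6878,82.227
6.8519,76.973
7.0200,72.052
7.1922,67.445
7.3687,63.132
7.5494,59.093
7.7346,55.311
7.9244,51.771
8.0180,50.138
8.1188,48.457
8.1680,47.665
8.2580,46.26
8.3180,45.354
8.3325,45.139
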