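symbol,Z,atomic_weight,density_g_cm3,kedge_keV
Al,13,26.9815,2.699,1.560
Ni,28,58.6934,8.908,8.333
Zr,40,91.224,6.506,17.998
Nb,41,92.9064,8.57,18.986
Mo,42,95.95,10.22,20.000
Rh,45,102.9055,12.41,23.220
Pd,46,106.42,12.02,24.350
Ag,47,107.8682,10.5,25.517
Sn,50,118.71,7.287,29.200
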