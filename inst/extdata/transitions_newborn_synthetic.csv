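from,N1,N2,N3,O1n,exit
N1,0.955,0.015,0.020,0.000,0.010
N2,0.000,0.940,0.040,0.000,0.020
N3,0.000,0.000,0.930,0.000,0.070
O1n,0.040,0.000,0.040,0.770,0.160
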