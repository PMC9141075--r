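from,O1a,O2,O3,exit
O1a,0.850,0.010,0.010,0.130
O2,0.250,0.600,0.050,0.100
O3,0.500,0.050,0.300,0.150
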