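type,rmin_half,epsilon
CT,1.9080,0.1094
CA,1.9080,0.0860
C,1.9080,0.0860
N,1.8240,0.1700
N3,1.8240,0.1700
O,1.6612,0.2100
O2,1.6612,0.2100
OH,1.7210,0.2104
S,2.0000,0.2500
H,0.6000,0.0157
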