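type,dg_ref,volume,lambda
C,0.000,14.7,3.5
CR,0.057,8.3,3.5
CH1E,-0.187,23.7,3.5
CH2E,0.372,22.4,3.5
CH3E,1.089,30.0,3.5
NH1,-5.950,11.2,3.5
NH3,-20.000,11.2,6.0
NC2,-10.000,11.2,6.0
O,-5.330,10.8,3.5
OH1,-6.700,10.8,3.5
OC,-10.000,10.8,6.0
S,-3.240,14.7,3.5
H,0.000,0.0,3.5
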