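channel,region
Fp1,F
Fp2,F
F3,F
Fz,F
F4,F
F7,L-T
T7,L-T
P7,L-T
F8,R-T
T8,R-T
P8,R-T
C3,P
Cz,P
C4,P
P3,P
Pz,P
P4,P
O1,O
O2,O
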