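channel,region
Fp1,F
Fp2,F
AF7,F
AF3,F
AF4,F
AF8,F
F7,F
F5,F
F3,F
F1,F
Fz,F
F2,F
F4,F
F6,F
F8,F
FC5,F
FC3,F
FC1,F
FC2,F
FC4,F
FC6,F
FT9,L-T
FT7,L-T
T7,L-T
TP9,L-T
TP7,L-T
FT10,R-T
FT8,R-T
T8,R-T
TP10,R-T
TP8,R-T
C5,P
C3,P
C1,P
Cz,P
C2,P
C4,P
C6,P
CP5,P
CP3,P
CP1,P
CPz,P
CP2,P
CP4,P
CP6,P
P7,P
P5,P
P3,P
P1,P
Pz,P
P2,P
P4,P
P6,P
P8,P
PO9,O
PO7,O
PO3,O
POz,O
PO4,O
PO8,O
PO10,O
O1,O
Oz,O
O2,O
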