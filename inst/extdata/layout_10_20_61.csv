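name,x,y
FP1,-0.4228,0.9
FPz,0,0.9
FP2,0.4228,0.9
AF7,-0.6732,0.72
AF3,-0.2244,0.72
AF4,0.2244,0.72
AF8,0.6732,0.72
F7,-0.8285,0.52
F5,-0.5918,0.52
F3,-0.3551,0.52
F1,-0.1184,0.52
F2,0.1184,0.52
F4,0.3551,0.52
F6,0.5918,0.52
F8,0.8285,0.52
FT7,-0.9366,0.26
FC5,-0.7025,0.26
FC3,-0.4683,0.26
FC1,-0.2342,0.26
FCz,0,0.26
FC2,0.2342,0.26
FC4,0.4683,0.26
FC6,0.7025,0.26
FT8,0.9366,0.26
T7,-0.97,0
C5,-0.7275,0
C3,-0.485,0
C1,-0.2425,0
Cz,0,0
C2,0.2425,0
C4,0.485,0
C6,0.7275,0
T8,0.97,0
TP7,-0.9366,-0.26
CP5,-0.7025,-0.26
CP3,-0.4683,-0.26
CP1,-0.2342,-0.26
CPz,0,-0.26
CP2,0.2342,-0.26
CP4,0.4683,-0.26
CP6,0.7025,-0.26
TP8,0.9366,-0.26
P7,-0.8285,-0.52
P5,-0.6214,-0.52
P3,-0.4143,-0.52
P1,-0.2071,-0.52
Pz,0,-0.52
P2,0.2071,-0.52
P4,0.4143,-0.52
P6,0.6214,-0.52
P8,0.8285,-0.52
PO7,-0.6732,-0.72
PO3,-0.3366,-0.72
POz,0,-0.72
PO4,0.3366,-0.72
PO8,0.6732,-0.72
O1,-0.4228,-0.9
Oz,0,-0.9
O2,0.4228,-0.9
TP9,-0.9348,-0.34
TP10,0.9348,-0.34
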