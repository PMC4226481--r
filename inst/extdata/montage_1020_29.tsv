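channel	x	y
F3	-0.34	0.54
F4	0.34	0.54
Fz	0.00	0.55
FC1	-0.20	0.30
FC2	0.20	0.30
FC5	-0.59	0.33
FC6	0.59	0.33
C3	-0.36	0.00
C4	0.36	0.00
Cz	0.00	0.00
T7	-0.72	0.00
T8	0.72	0.00
CP1	-0.20	-0.30
CP2	0.20	-0.30
CP5	-0.59	-0.33
CP6	0.59	-0.33
P3	-0.34	-0.54
P4	0.34	-0.54
Pz	0.00	-0.55
P7	-0.58	-0.48
P8	0.58	-0.48
PO3	-0.22	-0.72
PO4	0.22	-0.72
POz	0.00	-0.73
PO7	-0.43	-0.70
PO8	0.43	-0.70
O1	-0.20	-0.86
Oz	0.00	-0.90
O2	0.20	-0.86
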