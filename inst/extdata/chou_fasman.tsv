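aa	helix	sheet
A	1.42	0.83
C	0.70	1.19
D	1.01	0.54
E	1.51	0.37
F	1.13	1.38
G	0.57	0.75
H	1.00	0.87
I	1.08	1.60
K	1.16	0.74
L	1.21	1.30
M	1.45	1.05
N	0.67	0.89
P	0.57	0.55
Q	1.11	1.10
R	0.98	0.93
S	0.77	0.75
T	0.83	1.19
V	1.06	1.70
W	1.08	1.37
Y	0.69	1.47
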