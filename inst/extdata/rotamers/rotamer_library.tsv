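residue	chi1	chi2	chi3	chi4	probability
ALA	NA	NA	NA	NA	1.0
GLY	NA	NA	NA	NA	1.0
SER	62	NA	NA	NA	0.48
SER	-65	NA	NA	NA	0.29
SER	180	NA	NA	NA	0.22
CYS	-65	NA	NA	NA	0.50
CYS	180	NA	NA	NA	0.26
CYS	62	NA	NA	NA	0.23
THR	62	NA	NA	NA	0.49
THR	-60	NA	NA	NA	0.43
THR	-175	NA	NA	NA	0.07
VAL	175	NA	NA	NA	0.73
VAL	-60	NA	NA	NA	0.20
VAL	63	NA	NA	NA	0.06
ILE	-65	170	NA	NA	0.60
ILE	-57	-60	NA	NA	0.15
ILE	62	170	NA	NA	0.10
ILE	-177	165	NA	NA	0.08
LEU	-65	175	NA	NA	0.59
LEU	-177	65	NA	NA	0.29
LEU	-172	147	NA	NA	0.05
LEU	-85	65	NA	NA	0.04
MET	-65	-65	-70	NA	0.18
MET	-67	177	72	NA	0.12
MET	-67	177	-75	NA	0.11
MET	-67	177	180	NA	0.10
MET	-177	65	75	NA	0.08
MET	-177	180	75	NA	0.07
MET	62	180	75	NA	0.05
PHE	-65	90	NA	NA	0.44
PHE	-177	80	NA	NA	0.33
PHE	62	90	NA	NA	0.13
TYR	-65	90	NA	NA	0.43
TYR	-177	80	NA	NA	0.34
TYR	62	90	NA	NA	0.13
TRP	-65	95	NA	NA	0.32
TRP	-177	-95	NA	NA	0.16
TRP	-65	-5	NA	NA	0.15
TRP	62	-90	NA	NA	0.13
HIS	-65	-70	NA	NA	0.33
HIS	-177	-80	NA	NA	0.22
HIS	-65	165	NA	NA	0.14
HIS	62	-75	NA	NA	0.12
ASP	-70	-15	NA	NA	0.51
ASP	-177	0	NA	NA	0.21
ASP	62	0	NA	NA	0.16
ASN	-65	-20	NA	NA	0.33
ASN	-177	30	NA	NA	0.18
ASN	-65	120	NA	NA	0.12
ASN	62	-20	NA	NA	0.11
GLU	-65	-65	-40	NA	0.23
GLU	-67	177	0	NA	0.20
GLU	-177	65	10	NA	0.11
GLU	-177	180	0	NA	0.10
GLU	62	180	-20	NA	0.06
GLN	-65	-65	-40	NA	0.21
GLN	-67	177	0	NA	0.18
GLN	-177	65	0	NA	0.10
GLN	-177	180	20	NA	0.09
GLN	62	180	20	NA	0.06
LYS	-67	180	180	180	0.27
LYS	-65	-68	180	180	0.13
LYS	-177	180	180	180	0.12
LYS	-67	180	-68	180	0.09
LYS	-67	180	180	-65	0.08
LYS	62	180	180	180	0.06
ARG	-67	180	180	180	0.12
ARG	-67	180	180	-85	0.10
ARG	-177	180	180	180	0.09
ARG	-67	180	65	85	0.08
ARG	-67	-65	-65	-85	0.07
ARG	-177	180	65	85	0.06
ARG	62	180	180	180	0.05
PRO	30	-35	NA	NA	0.50
PRO	-30	35	NA	NA	0.45
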