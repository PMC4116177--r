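resname	rotamer	chi1	chi2	chi3	chi4
PHE	1	-65	90	NA	NA
PHE	2	180	90	NA	NA
PHE	3	62	90	NA	NA
PHE	4	-65	-85	NA	NA
PHE	5	180	-85	NA	NA
PHE	6	62	-85	NA	NA
TYR	1	-65	90	NA	NA
TYR	2	180	90	NA	NA
TYR	3	62	90	NA	NA
TYR	4	-65	-85	NA	NA
TYR	5	180	-85	NA	NA
TYR	6	62	-85	NA	NA
LEU	1	-65	65	NA	NA
LEU	2	180	65	NA	NA
LEU	3	62	65	NA	NA
LEU	4	-65	175	NA	NA
LEU	5	180	175	NA	NA
LEU	6	62	175	NA	NA
ILE	1	-65	-60	NA	NA
ILE	2	180	-60	NA	NA
ILE	3	62	-60	NA	NA
ILE	4	-65	170	NA	NA
ILE	5	180	170	NA	NA
ILE	6	62	170	NA	NA
MET	1	-65	-65	-75	NA
MET	2	180	-65	-75	NA
MET	3	62	-65	-75	NA
MET	4	-65	180	-75	NA
MET	5	180	180	-75	NA
MET	6	62	180	-75	NA
MET	7	-65	65	-75	NA
MET	8	180	65	-75	NA
MET	9	62	65	-75	NA
MET	10	-65	-65	75	NA
MET	11	180	-65	75	NA
MET	12	62	-65	75	NA
MET	13	-65	180	75	NA
MET	14	180	180	75	NA
MET	15	62	180	75	NA
MET	16	-65	65	75	NA
MET	17	180	65	75	NA
MET	18	62	65	75	NA
MET	19	-65	-65	180	NA
MET	20	180	-65	180	NA
MET	21	62	-65	180	NA
MET	22	-65	180	180	NA
MET	23	180	180	180	NA
MET	24	62	180	180	NA
MET	25	-65	65	180	NA
MET	26	180	65	180	NA
MET	27	62	65	180	NA
VAL	1	175	NA	NA	NA
VAL	2	-60	NA	NA	NA
VAL	3	63	NA	NA	NA
ALA	1	NA	NA	NA	NA
GLY	1	NA	NA	NA	NA
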