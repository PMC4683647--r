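cross_type	dam	sire	n_female	n_herm
H-SELF	LNF23	LNF23	9	44
H-SELF	LNF25	LNF25	17	36
H-SELF	LNF14	LNF14	15	15
FxH	LNF26	LNF23	4	8
FxH	LNF26	LNF25	29	21
FxH	LNF26	LNF14	6	4
FxH	LNF2	LNF23	11	9
FxH	LNF2	LNF25	20	22
FxH	LNF2	LNF14	7	10
FxH	LNF4	LNF23	17	23
FxH	LNF4	LNF25	11	18
FxH	LNF4	LNF14	3	4
HxH	LNF23	LNF25	1	3
HxH	LNF25	LNF23	5	17
HxH	LNF14	LNF23	5	22
HxH	LNF14	LNF25	1	1
HxH	LNF25	LNF14	0	0
HxH	LNF23	LNF14	0	0
H-SELF	MRD45	MRD45	3	13
H-SELF	MRD61	MRD61	0	43
H-SELF	MRD93	MRD93	8	31
FxH	MRD27	MRD45	10	8
FxH	MRD27	MRD61	11	20
FxH	MRD27	MRD93	11	8
FxH	MRD30	MRD45	5	6
FxH	MRD30	MRD61	11	12
FxH	MRD30	MRD93	8	11
FxH	MRD90	MRD45	13	12
FxH	MRD90	MRD61	10	18
FxH	MRD90	MRD93	15	23
HxH	MRD45	MRD61	0	11
HxH	MRD61	MRD45	1	13
HxH	MRD61	MRD93	0	20
HxH	MRD93	MRD61	0	0
HxH	MRD45	MRD93	0	7
HxH	MRD93	MRD45	0	4
FxH	MRD27	LNF23	13	4
FxH	MRD27	LNF25	18	17
FxH	MRD27	LNF14	10	4
FxH	MRD30	LNF23	15	11
FxH	MRD30	LNF25	20	13
FxH	MRD30	LNF14	9	7
FxH	MRD90	LNF23	24	20
FxH	MRD90	LNF25	20	26
FxH	MRD90	LNF14	17	22
FxH	LNF26	MRD45	0	13
FxH	LNF26	MRD61	0	15
FxH	LNF26	MRD93	15	6
FxH	LNF2	MRD45	0	18
FxH	LNF2	MRD61	0	5
FxH	LNF2	MRD93	21	7
FxH	LNF4	MRD45	0	14
FxH	LNF4	MRD61	0	15
FxH	LNF4	MRD93	35	17
HxH	MRD45	LNF23	0	29
HxH	MRD45	LNF25	0	18
HxH	MRD45	LNF14	0	0
HxH	MRD61	LNF23	0	25
HxH	MRD61	LNF25	0	15
HxH	MRD93	LNF23	6	21
HxH	MRD93	LNF25	0	3
HxH	MRD93	LNF14	0	0
HxH	LNF23	MRD45	0	0
HxH	LNF23	MRD61	0	1
HxH	LNF23	MRD93	2	2
HxH	LNF25	MRD45	0	0
HxH	LNF25	MRD61	0	0
HxH	LNF25	MRD93	0	0
HxH	LNF14	MRD45	2	2
HxH	LNF14	MRD61	0	3
HxH	LNF14	MRD93	0	0
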