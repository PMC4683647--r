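dam	sire	expected_ratio	chisq_printed	flagged_irreproducible	ratio_model_consistent	alt_ratio
LNF23	LNF23	1:3	2.7	TRUE	TRUE	NA
LNF25	LNF25	1:3	1.42	FALSE	TRUE	NA
LNF14	LNF14	1:3	4.6	TRUE	TRUE	7:9
LNF26	LNF23	1:1	1.33	FALSE	TRUE	NA
LNF26	LNF25	1:1	1.28	FALSE	TRUE	NA
LNF26	LNF14	1:1	0.4	FALSE	TRUE	NA
LNF2	LNF23	1:1	0.2	FALSE	TRUE	NA
LNF2	LNF25	1:1	0.1	FALSE	TRUE	NA
LNF2	LNF14	1:1	0.53	FALSE	TRUE	NA
LNF4	LNF23	1:1	0.9	FALSE	TRUE	NA
LNF4	LNF25	1:1	1.69	FALSE	TRUE	NA
LNF4	LNF14	1:1	0.14	FALSE	TRUE	NA
LNF23	LNF25	1:3	NA	FALSE	TRUE	NA
LNF25	LNF23	1:3	0.06	FALSE	TRUE	NA
LNF14	LNF23	1:3	0.61	FALSE	TRUE	NA
LNF14	LNF25	1:3	NA	FALSE	TRUE	NA
MRD45	MRD45	1:3	0.33	FALSE	TRUE	NA
MRD61	MRD61	1:3	14.33	FALSE	TRUE	0:1
MRD93	MRD93	1:3	0.42	FALSE	TRUE	NA
MRD27	MRD45	1:1	0.22	FALSE	TRUE	NA
MRD27	MRD61	1:1	2.61	FALSE	TRUE	NA
MRD27	MRD93	1:1	0.47	FALSE	TRUE	NA
MRD30	MRD45	1:1	0.09	FALSE	TRUE	NA
MRD30	MRD61	1:1	0.04	FALSE	TRUE	NA
MRD30	MRD93	1:1	0.47	FALSE	TRUE	NA
MRD90	MRD45	1:1	0.04	FALSE	TRUE	NA
MRD90	MRD61	1:1	2.29	FALSE	TRUE	NA
MRD90	MRD93	1:1	1.68	FALSE	TRUE	NA
MRD45	MRD61	0:1	0	FALSE	TRUE	NA
MRD61	MRD45	0:1	0	FALSE	TRUE	NA
MRD61	MRD93	0:1	0	FALSE	TRUE	NA
MRD45	MRD93	1:3	2.33	FALSE	FALSE	NA
MRD93	MRD45	1:3	NA	FALSE	FALSE	NA
MRD27	LNF23	1:1	4.76	FALSE	TRUE	NA
MRD27	LNF25	1:1	0.03	FALSE	TRUE	NA
MRD27	LNF14	1:1	2.57	FALSE	TRUE	NA
MRD30	LNF23	1:1	0.62	FALSE	TRUE	NA
MRD30	LNF25	1:1	1.48	FALSE	TRUE	NA
MRD30	LNF14	1:1	0.25	FALSE	TRUE	NA
MRD90	LNF23	1:1	0.36	FALSE	TRUE	NA
MRD90	LNF25	1:1	0.78	FALSE	TRUE	NA
MRD90	LNF14	1:1	0.64	FALSE	TRUE	NA
LNF26	MRD45	0:1	0	FALSE	TRUE	NA
LNF26	MRD61	0:1	0	FALSE	TRUE	NA
LNF26	MRD93	1:1	3.86	FALSE	TRUE	2:1
LNF2	MRD45	0:1	0	FALSE	TRUE	NA
LNF2	MRD61	0:1	0	FALSE	TRUE	NA
LNF2	MRD93	1:1	7	FALSE	TRUE	2:1
LNF4	MRD45	0:1	0	FALSE	TRUE	NA
LNF4	MRD61	0:1	0	FALSE	TRUE	NA
LNF4	MRD93	1:1	6.23	FALSE	TRUE	2:1
MRD45	LNF23	0:1	0	FALSE	TRUE	NA
MRD45	LNF25	0:1	0	FALSE	TRUE	NA
MRD61	LNF23	0:1	0	FALSE	TRUE	NA
MRD61	LNF25	0:1	0	FALSE	TRUE	NA
MRD93	LNF23	1:3	0.11	FALSE	TRUE	NA
MRD93	LNF25	1:3	NA	FALSE	TRUE	NA
LNF23	MRD61	0:1	NA	FALSE	TRUE	NA
LNF23	MRD93	1:3	NA	FALSE	TRUE	NA
LNF14	MRD45	1:3	NA	FALSE	TRUE	NA
LNF14	MRD61	0:1	NA	FALSE	TRUE	NA
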