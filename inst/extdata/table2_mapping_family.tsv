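id	family	sex	Fvb6_34763308	Fvb6_34763440	Fvb6_34763505	Fvb6_35142087	Fvb6_35142280	Fvb6_35142453	Fvb6_36607138
LNF23self_01	LNF23self	F	G	G	T	.	G	T	A
LNF23self_02	LNF23self	F	G	G	T	.	G	T	A
LNF23self_03	LNF23self	F	G	G	T	.	G	T	A
LNF23self_04	LNF23self	F	G	G	T	.	G	T	A
LNF23self_05	LNF23self	F	G	G	T	.	G	T	A
LNF23self_06	LNF23self	F	G	G	T	.	G	T	A/G
LNF23self_07	LNF23self	F	G	G	T	.	G	T	.
LNF23self_08	LNF23self	F	G/T	G/T	G/T	.	G	T	A
LNF23self_09	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_10	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_11	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_12	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_13	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_14	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_15	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_16	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_17	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_18	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_19	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_20	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_21	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_22	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_23	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_24	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_25	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_26	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_27	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A/G
LNF23self_28	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A
LNF23self_29	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	A
LNF23self_30	LNF23self	H	G/T	G/T	G/T	.	G/T	C/T	G
LNF23self_31	LNF23self	H	T	T	G	.	T	C	G
LNF23self_32	LNF23self	H	T	T	G	.	T	C	G
LNF23self_33	LNF23self	H	T	T	G	.	T	C	G
LNF23self_34	LNF23self	H	T	T	G	.	T	C	G
LNF23self_35	LNF23self	H	T	T	G	.	T	C	G
LNF23self_36	LNF23self	H	T	T	G	.	T	C	G
LNF23self_37	LNF23self	H	T	T	G	.	T	C	G
LNF23self_38	LNF23self	H	T	T	G	.	T	C	G
LNF23self_39	LNF23self	H	T	T	G	.	T	C	G
LNF23self_40	LNF23self	H	T	G/T	G	.	T	C	G
LNF23self_41	LNF23self	H	T	T	G	.	T	C	A/G
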