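id	population	sex	mitotype	LG4	LG6	LGx
MRD93	OR-MRD	H	B	mfmf	Rr	TT
MRD61	OR-MRD	H	C	mfmf	RR	TT
MRD45	OR-MRD	H	C	mfmf	RR	Tt
MRD30	OR-MRD	F	C	MSmf	RR	TT
MRD27	OR-MRD	F	C	MSmf	RR	TT
MRD90	OR-MRD	F	C	MSmf	RR	TT
LNF23	NM-LNF	H	F	mfmf	Rr	TT
LNF25	NM-LNF	H	F	mfmf	Rr	TT
LNF14	NM-LNF	H	F	mfmf	Rr	Tt
LNF2	NM-LNF	F	F	mfmf	rr	TT
LNF4	NM-LNF	F	F	mfmf	rr	TT
LNF26	NM-LNF	F	F	mfmf	rr	TT
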