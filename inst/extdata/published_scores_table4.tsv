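target	uniprot	functional_group	disease	glyph	score_pct
FAS	P25445	Apoptosis	CIDP	++	72
FAS	P25445	Apoptosis	MMN	+	64
FAS	P25445	Apoptosis	GBS	+	64
FAS	P25445	Apoptosis	MG	+	41
FAS	P25445	Apoptosis	GO	+	39
FAS	P25445	Apoptosis	ITP	++	74
FAS	P25445	Apoptosis	KD	+	46
FCGR3A	P08637	B cell-mediated	CIDP	+++	86
FCGR3A	P08637	B cell-mediated	MMN	+++	85
FCGR3A	P08637	B cell-mediated	GBS	-	11
FCGR3A	P08637	B cell-mediated	MG	+	52
FCGR3A	P08637	B cell-mediated	GO	-	20
FCGR3A	P08637	B cell-mediated	ITP	-	27
FCGR3A	P08637	B cell-mediated	KD	-	37
FCGR3B	O75015	B cell-mediated	CIDP	++	76
FCGR3B	O75015	B cell-mediated	MMN	+++	93
FCGR3B	O75015	B cell-mediated	GBS	-	31
FCGR3B	O75015	B cell-mediated	MG	+	69
FCGR3B	O75015	B cell-mediated	GO	-	17
FCGR3B	O75015	B cell-mediated	ITP	-	12
FCGR3B	O75015	B cell-mediated	KD	+	43
FCGR2A	P12318	B cell-mediated	CIDP	+	62
FCGR2A	P12318	B cell-mediated	MMN	+	44
FCGR2A	P12318	B cell-mediated	GBS	+	61
FCGR2A	P12318	B cell-mediated	MG	+	71
FCGR2A	P12318	B cell-mediated	GO	+	47
FCGR2A	P12318	B cell-mediated	ITP	+	71
FCGR2A	P12318	B cell-mediated	KD	+++	83
TNFSF13	O75888	B cell-mediated	CIDP	+	40
TNFSF13	O75888	B cell-mediated	MMN	-	8
TNFSF13	O75888	B cell-mediated	GBS	-	35
TNFSF13	O75888	B cell-mediated	MG	+	44
TNFSF13	O75888	B cell-mediated	GO	-	24
TNFSF13	O75888	B cell-mediated	ITP	+++	90
TNFSF13	O75888	B cell-mediated	KD	+	66
TNFSF13B	Q9Y275	B cell-mediated	CIDP	-	22
TNFSF13B	Q9Y275	B cell-mediated	MMN	-	3
TNFSF13B	Q9Y275	B cell-mediated	GBS	-	5
TNFSF13B	Q9Y275	B cell-mediated	MG	-	28
TNFSF13B	Q9Y275	B cell-mediated	GO	-	15
TNFSF13B	Q9Y275	B cell-mediated	ITP	+++	79
TNFSF13B	Q9Y275	B cell-mediated	KD	++	76
SIGLEC9	Q9Y336	Antigen presentation	CIDP	-	14
SIGLEC9	Q9Y336	Antigen presentation	MMN	-	16
SIGLEC9	Q9Y336	Antigen presentation	GBS	-	20
SIGLEC9	Q9Y336	Antigen presentation	MG	-	18
SIGLEC9	Q9Y336	Antigen presentation	GO	++	73
SIGLEC9	Q9Y336	Antigen presentation	ITP	-	14
SIGLEC9	Q9Y336	Antigen presentation	KD	-	34
C5	P01031	Complement system	CIDP	+++	86
C5	P01031	Complement system	MMN	++	72
C5	P01031	Complement system	GBS	+++	93
C5	P01031	Complement system	MG	+++	82
C5	P01031	Complement system	GO	-	9
C5	P01031	Complement system	ITP	-	27
C5	P01031	Complement system	KD	++	77
C3	P01024	Complement system	CIDP	++	77
C3	P01024	Complement system	MMN	+	63
C3	P01024	Complement system	GBS	+	59
C3	P01024	Complement system	MG	+++	86
C3	P01024	Complement system	GO	-	11
C3	P01024	Complement system	ITP	++	72
C3	P01024	Complement system	KD	+++	85
C4B	P0C0L5	Complement system	CIDP	-	38
C4B	P0C0L5	Complement system	MMN	+++	82
C4B	P0C0L5	Complement system	GBS	+++	92
C4B	P0C0L5	Complement system	MG	++	72
C4B	P0C0L5	Complement system	GO	-	7
C4B	P0C0L5	Complement system	ITP	+++	84
C4B	P0C0L5	Complement system	KD	+	67
C1QA	P02745	Complement system	CIDP	-	28
C1QA	P02745	Complement system	MMN	+	58
C1QA	P02745	Complement system	GBS	+	41
C1QA	P02745	Complement system	MG	+	40
C1QA	P02745	Complement system	GO	++	71
C1QA	P02745	Complement system	ITP	+	47
C1QA	P02745	Complement system	KD	+	54
C1R	P00736	Complement system	CIDP	-	23
C1R	P00736	Complement system	MMN	+	40
C1R	P00736	Complement system	GBS	++	71
C1R	P00736	Complement system	MG	-	32
C1R	P00736	Complement system	GO	+	68
C1R	P00736	Complement system	ITP	+	41
C1R	P00736	Complement system	KD	-	18
C1S	P09871	Complement system	CIDP	-	22
C1S	P09871	Complement system	MMN	+	40
C1S	P09871	Complement system	GBS	++	71
C1S	P09871	Complement system	MG	-	33
C1S	P09871	Complement system	GO	+	60
C1S	P09871	Complement system	ITP	+	42
C1S	P09871	Complement system	KD	-	15
HLA-DPA1	P20036	HLA	CIDP	+++	80
HLA-DPA1	P20036	HLA	MMN	+	68
HLA-DPA1	P20036	HLA	GBS	+++	81
HLA-DPA1	P20036	HLA	MG	+	42
HLA-DPA1	P20036	HLA	GO	-	36
HLA-DPA1	P20036	HLA	ITP	++	72
HLA-DPA1	P20036	HLA	KD	+	41
HLA-DQA1	P01909	HLA	CIDP	++	76
HLA-DQA1	P01909	HLA	MMN	+	41
HLA-DQA1	P01909	HLA	GBS	+	56
HLA-DQA1	P01909	HLA	MG	++	73
HLA-DQA1	P01909	HLA	GO	-	36
HLA-DQA1	P01909	HLA	ITP	+	71
HLA-DQA1	P01909	HLA	KD	+	39
HLA-DRA	P01903	HLA	CIDP	++	72
HLA-DRA	P01903	HLA	MMN	+	44
HLA-DRA	P01903	HLA	GBS	+	50
HLA-DRA	P01903	HLA	MG	+	39
HLA-DRA	P01903	HLA	GO	++	71
HLA-DRA	P01903	HLA	ITP	+	49
HLA-DRA	P01903	HLA	KD	-	33
HLA-DPB1	P04440	HLA	CIDP	++	71
HLA-DPB1	P04440	HLA	MMN	-	22
HLA-DPB1	P04440	HLA	GBS	-	9
HLA-DPB1	P04440	HLA	MG	-	36
HLA-DPB1	P04440	HLA	GO	-	37
HLA-DPB1	P04440	HLA	ITP	+	51
HLA-DPB1	P04440	HLA	KD	-	18
HLA-B	P01889	HLA	CIDP	+	51
HLA-B	P01889	HLA	MMN	-	23
HLA-B	P01889	HLA	GBS	-	26
HLA-B	P01889	HLA	MG	+	46
HLA-B	P01889	HLA	GO	-	26
HLA-B	P01889	HLA	ITP	-	30
HLA-B	P01889	HLA	KD	++	71
CLEC4A	Q9UMR7	Innate immunity	CIDP	++	73
CLEC4A	Q9UMR7	Innate immunity	MMN	+	65
CLEC4A	Q9UMR7	Innate immunity	GBS	++	71
CLEC4A	Q9UMR7	Innate immunity	MG	++	72
CLEC4A	Q9UMR7	Innate immunity	GO	++	72
CLEC4A	Q9UMR7	Innate immunity	ITP	++	72
CLEC4A	Q9UMR7	Innate immunity	KD	++	72
CD209	Q9NNX6	Innate immunity	CIDP	++	71
CD209	Q9NNX6	Innate immunity	MMN	-	3
CD209	Q9NNX6	Innate immunity	GBS	+	63
CD209	Q9NNX6	Innate immunity	MG	+	71
CD209	Q9NNX6	Innate immunity	GO	++	71
CD209	Q9NNX6	Innate immunity	ITP	+	57
CD209	Q9NNX6	Innate immunity	KD	++	73
CCR5	P51681	Innate immunity, T cell-related	CIDP	+++	93
CCR5	P51681	Innate immunity, T cell-related	MMN	-	36
CCR5	P51681	Innate immunity, T cell-related	GBS	+	67
CCR5	P51681	Innate immunity, T cell-related	MG	+	39
CCR5	P51681	Innate immunity, T cell-related	GO	+	69
CCR5	P51681	Innate immunity, T cell-related	ITP	+	66
CCR5	P51681	Innate immunity, T cell-related	KD	+	43
CD4	P01730	T cell-related	CIDP	++	71
CD4	P01730	T cell-related	MMN	+	50
CD4	P01730	T cell-related	GBS	+++	87
CD4	P01730	T cell-related	MG	+	63
CD4	P01730	T cell-related	GO	-	38
CD4	P01730	T cell-related	ITP	+	40
CD4	P01730	T cell-related	KD	+	57
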