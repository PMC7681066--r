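gene	uniprot	hazard_ratio	p_value
A2M	A2MG	1.18	<0.0001
B2M	B2MG	1.20	<0.0001
CD163	C163A	1.03	0.2891
ALCAM	CD166	1.14	<0.0001
CD5L	CD5L	1.08	0.0109
CFD	CFAD	1.16	<0.0001
C7	CO7	1.32	<0.0001
C9	CO9	1.22	<0.0001
CRP	CRP	1.17	<0.0001
CSF1R	CSF1R	1.15	<0.0001
CST3	CYTC	1.21	<0.0001
FCGR3A	FCG3A	1.14	<0.0001
FCGBP	FCGBP	1.14	<0.0001
HPR	HPTR	1.11	0.0001
IGHG3	IGHG3	1.10	0.0001
LGALS3BP	LG3BP	1.16	<0.0001
MMP2	MMP2	1.13	<0.0001
MCAM	MUC18	1.07	0.0142
IGHM	IGHM	1.08	0.0030
NRP1	NRP1	1.14	<0.0001
GPLD1	PHLD	1.15	<0.0001
PTGDS	PTGDS	1.16	<0.0001
S100A9	S10A9	1.13	<0.0001
F2	THRB	1.11	0.0001
VWF	VWF	1.15	<0.0001
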