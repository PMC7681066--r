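gene	uniprot	n_peptides	protein_name	meta_fold	meta_p
C9	CO9	19	Complement component C9	-1.217	0.0002
S100A9	S10A9	3	Protein S100-A9	-1.206	0.0700
CD163	C163A	5	Scavenger receptor cysteine-rich type 1 protein M130	-1.179	0.0179
CRP	CRP	6	C-reactive protein	-1.170	0.0183
IGHM	IGHM	19	Immunoglobulin heavy constant mu	-1.157	0.0002
C7	CO7	49	Complement component C7	-1.150	0.0001
FCGR3A	FCG3A	4	Low affinity immunoglobulin gamma Fc region receptor III-A	-1.148	0.0984
LGALS3BP	LG3BP	14	Galectin-3-binding protein	-1.148	0.0002
NRP1	NRP1	3	Neuropilin-1	-1.140	0.0966
ALCAM	CD166	4	CD166 antigen	-1.139	0.0535
GPLD1	PHLD	7	Phosphatidylinositol-glycan-specific phospholipase D	-1.136	0.0239
B2M	B2MG	7	Beta-2-microglobulin	-1.133	0.0133
A2M	A2MG	21	Alpha-2-macroglobulin	-1.133	0.0002
MMP2	MMP2	5	72 kDa type IV collagenase	-1.132	0.0286
VWF	VWF	58	von Willebrand factor	-1.120	0.0001
CSF1R	CSF1R	5	Macrophage colony-stimulating factor 1 receptor	-1.119	0.0390
HPR	HPTR	13	Haptoglobin-related protein	-1.117	0.0003
CFD	CFAD	7	Complement factor D	-1.111	0.0078
CD5L	CD5L	6	CD5 antigen-like	-1.111	0.0788
FCGBP	FCGBP	34	IgGFc-binding protein	-1.108	0.0001
IGHG3	IGHG3	13	Immunoglobulin heavy constant gamma 3	-1.106	0.0014
F2	THRB	53	Prothrombin	-1.104	0.0001
CST3	CYTC	7	Cystatin-C	-1.102	0.0569
PTGDS	PTGDS	4	Prostaglandin-H2 D-isomerase	-1.101	0.0826
MCAM	MUC18	7	Cell surface glycoprotein MUC18	-1.101	0.0445
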