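pair_id	ligand	receptor
CD99_PILRA	CD99	PILRA
CD52_SIGLEC10	CD52	SIGLEC10
TGFB1_TGFBR1	TGFB1	TGFBR1
CD40LG_CD40	CD40LG	CD40
IL2_IL2RA	IL2	IL2RA
CCL5_CCR5	CCL5	CCR5
CXCL12_CXCR4	CXCL12	CXCR4
TNF_TNFRSF1A	TNF	TNFRSF1A
IFNG_IFNGR1	IFNG	IFNGR1
IL6_IL6R	IL6	IL6R
VEGFA_FLT1	VEGFA	FLT1
KITLG_KIT	KITLG	KIT
FLT3LG_FLT3	FLT3LG	FLT3
CSF1_CSF1R	CSF1	CSF1R
ICAM1_ITGAL	ICAM1	ITGAL
VCAM1_ITGA4	VCAM1	ITGA4
CD274_PDCD1	CD274	PDCD1
CD80_CTLA4	CD80	CTLA4
LGALS9_HAVCR2	LGALS9	HAVCR2
CCL2_CCR2	CCL2	CCR2
CX3CL1_CX3CR1	CX3CL1	CX3CR1
JAG1_NOTCH1	JAG1	NOTCH1
DLL1_NOTCH1	DLL1	NOTCH1
IL10_IL10RA	IL10	IL10RA
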