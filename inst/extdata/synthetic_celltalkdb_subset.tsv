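lr_pair	ligand_gene_symbol	receptor_gene_symbol	evidence
COL18A1_ITGB5	COL18A1	ITGB5	literature
GCG_DPP4	GCG	DPP4	literature
CXCL12_AVPR1A	CXCL12	AVPR1A	literature
L1CAM_EGFR	L1CAM	EGFR	literature
L1CAM_ERBB2	L1CAM	ERBB2	literature
HSPG2_FGFR1	HSPG2	FGFR1	literature
MMP2_FGFR1	MMP2	FGFR1	literature
FN1_ITGA6	FN1	ITGA6	literature
FN1_SDC2	FN1	SDC2	literature
GNAI2_IGF1R	GNAI2	IGF1R	literature
JAG1_NOTCH2	JAG1	NOTCH2	literature
TFPI_LRP1	TFPI	LRP1	literature
EREG_EGFR	EREG	EGFR	literature
EREG_ERBB2	EREG	ERBB2	literature
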