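PPAR_SIGNALING	PPAR signaling pathway	PPARG	ACOX2	FABP5	FABP4	ACSL3	ACSL4
HIF1_SIGNALING	HIF-1 signaling pathway	IGF1R	ALDOC	PIK3R1	PFKM	PFKL
GLYCOLYSIS	Glycolysis / gluconeogenesis	LDHA	PKM	ALDOC	PFKL	PFKM
FATTY_ACID_DEGRADATION	Fatty acid degradation	ACOX2	ECHS1	HADHB	HADH	ACAT1	ACAT2
OXPHOS	Oxidative phosphorylation	NDUFS8	UQCRB	NDUFB8	NDUFA2	COX6B1	UQCR10	COX6A1
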