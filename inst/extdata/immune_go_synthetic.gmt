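IMMUNE_INFILTRATION_SYNTHETIC	synthetic stand-in for a Gene Ontology immune-infiltration signature	FAS	NCAM1	CCL2	CD14	CXCL12	CCL5	CD2	HLA-DRA	C1QA	CD3E	PTPRC	CSF1R
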