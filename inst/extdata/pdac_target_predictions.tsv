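mirna_id	gene_symbol	binding_probability	region	validated	source
hsa-miR-143-5p	GSTM3	0.99	3UTR	true	published-cohort
hsa-miR-181c-5p	PEBP1	0.99	3UTR	true	published-cohort
hsa-miR-181d-5p	PEBP1	0.99	3UTR	true	published-cohort
hsa-miR-210-3p	ERP27	0.99	3UTR	true	published-cohort
hsa-miR-214-5p	TBL2	0.99	3UTR	true	published-cohort
hsa-miR-21-5p	DDAH1	0.99	3UTR	true	published-cohort
hsa-miR-331-5p	DDAH1	0.99	3UTR	true	published-cohort
hsa-miR-4742-5p	CSRP1	0.99	3UTR	true	published-cohort
hsa-miR-4742-5p	S100A16	0.99	3UTR	true	published-cohort
hsa-miR-4742-5p	SOD2	0.99	3UTR	true	published-cohort
hsa-miR-509-5p	COTL1	0.99	3UTR	true	published-cohort
hsa-miR-509-5p	LRPAP1	0.99	3UTR	true	published-cohort
hsa-miR-509-5p	SLC4A2	0.99	3UTR	true	published-cohort
hsa-miR-125b-2-3p	SUGT1	0.99	3UTR	true	published-cohort
hsa-miR-206	PPIB	0.99	3UTR	true	published-cohort
hsa-miR-206	SLC25A22	0.99	3UTR	true	published-cohort
hsa-miR-615-3p	DPP3	0.99	3UTR	true	published-cohort
hsa-miR-615-3p	GANAB	0.99	3UTR	true	published-cohort
hsa-miR-708-5p	RANBP2	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	AKR7A2	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	ATP1B3	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	CPM	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	FKBP15	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	RAB1A	0.99	3UTR	true	published-cohort
hsa-miR-2467-3p	UGGT1	0.99	3UTR	true	published-cohort
hsa-miR-378e	TXNL1	0.99	3UTR	true	published-cohort
hsa-miR-6778-5p	ATP5F1A	0.99	3UTR	true	published-cohort
hsa-miR-4534	CALR	0.99	3UTR	true	published-cohort
hsa-miR-4534	CAPZA1	0.99	3UTR	true	published-cohort
hsa-miR-4534	OLA1	0.99	3UTR	true	published-cohort
hsa-miR-4743-5p	CYP20A1	0.99	3UTR	true	published-cohort
hsa-miR-222-3p	GNAI3	0.99	3UTR	true	published-cohort
hsa-miR-222-3p	RECK	0.99	3UTR	true	published-cohort
hsa-miR-222-3p	SOD2	0.99	3UTR	true	published-cohort
hsa-miR-222-3p	TOM1	0.99	3UTR	true	published-cohort
hsa-miR-3154	HSP90B1	0.99	3UTR	true	published-cohort
hsa-miR-6831-5p	PLD3	0.99	3UTR	true	published-cohort
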