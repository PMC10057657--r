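gene_symbol	comparison	fraction	fold_change	p_value
GSTM3	TvN	membrane	-2.04	6.48e-3
GSTM3	F1vT	cytosolic	-15.16	6.46e-3
PEBP1	TvN	membrane	-3.20	1.19e-2
PEBP1	TvN	cytosolic	-2.90	1.33e-3
PEBP1	F1vT	membrane	-2.10	1.04e-2
PEBP1	F1vT	cytosolic	-3.50	3.77e-5
ERP27	TvN	membrane	-21.19	9.29e-4
TBL2	TvN	cytosolic	-13.95	4.01e-3
DDAH1	TvN	membrane	-2.13	1.92e-3
DDAH1	F1vT	cytosolic	4.16	3.84e-4
CSRP1	TvN	membrane	3.11	1.39e-3
CSRP1	TvN	cytosolic	2.34	1.31e-2
S100A16	TvN	membrane	4.20	1.12e-2
S100A16	F1vT	membrane	3.57	8.51e-4
SOD2	TvN	membrane	2.29	5.88e-3
SOD2	F1vT	membrane	-4.84	5.06e-6
SOD2	F1vT	cytosolic	-22.02	2.29e-9
COTL1	TvN	membrane	2.23	3.83e-2
COTL1	F1vT	cytosolic	8.77	1.61e-4
LRPAP1	TvN	membrane	2.21	3.10e-3
LRPAP1	F1vT	membrane	-2.37	1.53e-3
SLC4A2	TvN	membrane	6.03	3.11e-3
SLC4A2	F1vT	membrane	-1.98	5.14e-3
SUGT1	F1vT	cytosolic	3.19	9.56e-4
PPIB	TvN	cytosolic	-3.55	5.45e-3
PPIB	F1vT	membrane	-1.94	2.55e-2
PPIB	F1vT	cytosolic	-3.30	1.64e-2
SLC25A22	TvN	membrane	-2.77	1.19e-2
DPP3	TvN	membrane	2.53	2.66e-3
DPP3	F1vT	membrane	-1.91	1.20e-2
DPP3	F1vT	cytosolic	2.25	3.86e-4
GANAB	TvN	membrane	1.67	7.26e-3
GANAB	F1vT	membrane	-2.04	2.12e-4
RANBP2	F1vT	cytosolic	1.93	8.16e-3
AKR7A2	TvN	cytosolic	-2.09	1.56e-3
AKR7A2	F1vT	membrane	-1.81	1.01e-2
ATP1B3	TvN	membrane	1.88	3.03e-2
ATP1B3	F1vT	membrane	-2.26	1.59e-2
CPM	F1vT	membrane	-5.55	1.31e-2
FKBP15	F1vT	membrane	-4.64	5.12e-3
RAB1A	TvN	cytosolic	-3.33	4.87e-3
UGGT1	F1vT	membrane	-1.80	1.91e-2
TXNL1	F1vT	membrane	-2.54	2.30e-3
ATP5F1A	TvN	membrane	-2.19	9.76e-3
ATP5F1A	TvN	cytosolic	-2.70	1.53e-3
CALR	F1vT	membrane	-2.18	1.52e-4
CAPZA1	F1vT	membrane	-2.05	2.49e-3
CYP20A1	F1vT	membrane	-2.50	6.46e-3
GNAI3	F1vT	membrane	-2.56	3.85e-4
HSP90B1	TvN	membrane	-6.63	4.34e-3
HSP90B1	F1vT	membrane	-1.72	1.11e-2
OLA1	TvN	membrane	-4.41	3.21e-4
PLD3	F1vT	membrane	-3.55	1.13e-3
RECK	F1vT	membrane	-12.65	9.53e-8
TOM1	F1vT	membrane	-1.93	3.90e-2
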