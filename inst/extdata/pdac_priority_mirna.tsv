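mirna_id	comparison	fold_change	p_value
hsa-miR-21-3p	TvN	12.89	1.20e-3
hsa-miR-708-5p	TvN	9.15	6.70e-3
hsa-miR-181c-5p	TvN	8.52	3.00e-3
hsa-miR-125b-1-3p	TvN	6.95	3.18e-2
hsa-miR-21-5p	TvN	6.89	1.58e-2
hsa-miR-331-5p	TvN	6.81	3.60e-3
hsa-miR-210-3p	TvN	6.73	6.60e-3
hsa-miR-181d-5p	TvN	6.51	2.28e-2
hsa-miR-214-5p	TvN	6.3	1.02e-2
hsa-miR-143-5p	TvN	5.55	2.00e-4
hsa-mir-375	TvN	-1.67	3.16e-2
hsa-miR-3618	TvN	-1.76	4.70e-2
hsa-miR-509-5p	TvN	-1.85	1.30e-3
hsa-mir-6722	TvN	-2	4.62e-2
hsa-miR-4742-5p	TvN	-2.06	2.15e-2
hsa-mir-139	TvN	-2.2	4.92e-2
hsa-miR-451a	TvN	-2.93	3.50e-3
hsa-miR-139-5p	TvN	-4.51	1.20e-3
hsa-miR-486-5p	TvN	-4.65	1.33e-2
hsa-miR-148a-5p	TvN	-8.15	4.08e-2
hsa-miR-206	F1vT	26.01	8.59e-5
hsa-miR-4521	F1vT	24.27	4.48e-6
hsa-miR-6872-5p	F1vT	21.19	1.35e-7
hsa-miR-1290	F1vT	15.4	6.80e-3
hsa-miR-486-5p	F1vT	12.48	1.40e-3
hsa-miR-615-3p	F1vT	10.81	5.59e-5
hsa-miR-203a	F1vT	9.43	2.30e-3
hsa-miR-6778-5p	F1vT	8.56	5.42e-8
hsa-miR-2467-3p	F1vT	7.91	2.01e-8
hsa-miR-139-5p	F1vT	6.7	2.78e-6
hsa-miR-409-3p	F1vT	-11.45	1.47e-6
hsa-miR-146b-3p	F1vT	-12.7	6.39e-6
hsa-miR-217	F1vT	-13.39	1.98e-2
hsa-miR-503-5p	F1vT	-14.24	2.30e-3
hsa-miR-1271-5p	F1vT	-17.01	1.88e-6
hsa-miR-125b-2-3p	F1vT	-21.33	6.58e-7
hsa-miR-708-5p	F1vT	-21.66	2.00e-3
hsa-miR-487b-3p	F1vT	-34.33	1.31e-9
hsa-miR-424-3p	F1vT	-56.66	2.27e-6
hsa-miR-432-5p	F1vT	-113.44	2.10e-13
hsa-miR-6831-5p	TvN	4.82	2.16e-2
hsa-miR-6831-5p	F1vT	1.81	1.32e-2
hsa-miR-222-3p	TvN	1.99	7.10e-3
hsa-miR-222-3p	F1vT	2.27	2.41e-2
hsa-miR-4534	TvN	1.92	4.76e-2
hsa-miR-4534	F1vT	1.83	3.49e-2
hsa-miR-4743-5p	TvN	1.87	1.12e-2
hsa-miR-4743-5p	F1vT	1.94	2.20e-3
hsa-miR-3154	TvN	1.86	3.12e-2
hsa-miR-3154	F1vT	5.14	1.60e-5
hsa-miR-3935	TvN	1.85	2.99e-2
hsa-miR-3935	F1vT	2.5	1.59e-2
hsa-miR-378e	F1vT	4.2	1.10e-3
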