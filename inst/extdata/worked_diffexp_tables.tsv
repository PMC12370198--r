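table	comparison	gene_id	group_stat	reference_stat	fc	log2_fc	zscore	pval	regulation	robust
1	Sarcoma vs other	NECTIN4	0.40	22.50	0.02	-5.81	-4.01	2.9894E-05	down	TRUE
1	Sarcoma vs other	B7-H4	0.10	1.50	0.07	-3.91	-2.63	4.2311E-03	down	TRUE
1	Sarcoma vs other	CD70	6.00	1.00	6.00	2.58	2.07	1.9363E-02	up	FALSE
1	Melanoma vs other human	NECTIN4	0.50	22.50	0.02	-5.49	-4.30	8.5662E-06	down	TRUE
1	Melanoma vs other human	B7-H4	0.10	1.50	0.07	-3.91	-3.02	1.2592E-03	down	TRUE
1	HCC vs other	FGL-1	530.00	0.10	5300.00	12.37	4.23	1.1564E-05	up	TRUE
1	HCC vs other	Arginase 1	335.00	0.20	1675.00	10.71	3.68	1.1883E-04	up	TRUE
1	HCC vs other	NECTIN4	0.20	22.50	0.01	-6.81	-2.20	1.3918E-02	down	TRUE
1	Gynecological vs other	B7-H4	86.50	1.50	57.67	5.85	5.30	5.9158E-08	up	FALSE
1	Gastric cluster vs other	B7-H4	0.40	1.50	0.27	-1.91	-3.14	8.3576E-04	down	TRUE
1	Gastric cluster vs other	NECTIN4	10.00	22.50	0.44	-1.17	-1.88	3.0173E-02	down	FALSE
1	Gastric cluster vs other	GAL-9	68.00	31.50	2.16	1.11	2.04	2.0919E-02	up	FALSE
1	Gastric cluster vs other	CD70	2.00	1.00	2.00	1.00	1.85	3.2445E-02	up	TRUE
1	Lymphomas vs other	BTLA	29.00	0.40	72.50	6.18	1.66	4.8874E-02	up	FALSE
1	Lymphomas vs other	NECTIN4	0.50	22.50	0.02	-5.49	-3.24	5.8839E-04	down	TRUE
1	Lymphomas vs other	CD155	4.50	36.50	0.12	-3.02	-2.21	1.3671E-02	down	TRUE
1	Lymphomas vs other	B7-H3	7.00	55.00	0.13	-2.97	-2.19	1.4359E-02	down	TRUE
1	Brain cancers vs other	NECTIN4	0.15	22.50	0.01	-7.23	-3.17	7.5006E-04	down	TRUE
1	Brain cancers vs other	IDO	0.20	7.50	0.03	-5.23	-2.12	1.7039E-02	down	FALSE
1	Brain cancers cluster with MEL and RCC vs other	NECTIN4	0.20	22.50	0.01	-6.81	-5.08	1.8943E-07	down	TRUE
1	Brain cancers cluster with MEL and RCC vs other	SIRPA	153.50	48.50	3.16	1.66	1.68	4.6889E-02	up	FALSE
1	SCC and TCC vs other	GITR	27.00	4.50	6.00	2.58	2.78	2.6858E-03	up	FALSE
1	SCC and TCC vs other	NECTIN4	105.50	22.50	4.69	2.23	2.33	9.9524E-03	up	FALSE
1	SCC and TCC vs other	B7-H4	6.00	1.50	4.00	2.00	2.03	2.0954E-02	up	FALSE
1	Carcinomas vs other	B7-H4	7.00	1.50	4.67	2.22	5.09	1.7518E-07	up	FALSE
1	Carcinomas vs other	NECTIN4	43.50	22.50	1.93	0.95	2.05	2.0195E-02	up	FALSE
1	Adenocarcinomas vs other	B7-H4	9.00	1.50	6.00	2.58	4.61	2.0487E-06	up	FALSE
1	Adenocarcinomas vs other	ICOS	2.00	0.90	2.22	1.15	1.77	3.8458E-02	up	FALSE
1	Gynecological adenocarcinomas vs other adenocarcinomas	IDO	30.50	9.00	3.39	1.76	3.89	4.9942E-05	up	FALSE
1	Gastric adenocarcinomas vs other adenocarcinomas	B7-H4	0.40	66.00	0.01	-7.37	-5.73	4.9198E-09	down	TRUE
2	Canine vs Human	FGL-1	4.78	0.10	47.75	5.58	2.61	4.5128E-03	up	FALSE
2	Canine vs Human	Arginase 1	5.21	0.20	26.04	4.70	2.18	1.4554E-02	up	FALSE
2	Canine vs Human	NECTIN4	0.77	18.00	0.04	-4.55	-2.36	9.2459E-03	down	FALSE
2	Canine vs Human	A2AR	4.27	0.20	21.33	4.41	2.04	2.0641E-02	up	TRUE
2	Canine vs Human	OX40L	0.32	3.00	0.11	-3.24	-1.71	4.3182E-02	down	FALSE
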