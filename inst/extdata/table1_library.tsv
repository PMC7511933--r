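id	sequence	modifications	enzyme_class	target_enzymes	cleavage_index	phospho_position	printed_substrate_mass	printed_substrate_int	product1_seq	printed_product1_mass	printed_product1_int	product2_seq	printed_product2_mass	printed_product2_int
1	GTPGPQGLLGAPGI		protease	MMP	7		1234.42	-	GTPGPQG	612.64	-	LLGAPGI	639.80	-
2	GDQGPPGIPGQPGF		protease	MMP	7		1323.44	-	GDQGPPG	626.62	-	IPGQPGF	714.82	-
3	GLAQPVGINTSTTC		protease	MMP	7		1361.52	+	GLAQPVG	640.74	-	INTSTTC	738.81	-
4	GQGPGPKRGTEPKV		protease	Kallikrein-related peptidases	7		1407.58	+++	GQGPGPK	639.71	+	RGTEPKV	785.87	+
5	KSYELPDGQVITIG		protease	Caspase	7		1519.71	-	KSYELPD	850.92	-	GQVITIG	686.79	-
6	VSRLRAYLLPAPPA		protease	MMP 2	7		1523.87	++	VSRLRAY	864.02	+	LLAAPPA	677.85	+
7	AIQTVADGLKKQEE		protease	Caspase	7		1529.69	+	AIQTVAD	716.79	-	GLKKQEE	830.90	+
8	PGFSPFRSSRIGEI		protease	Kallikrein-related peptidases	7		1549.77	++	PGFSPFR	806.92	+	SSRIGEI	760.85	+
9	MGRGHARLVHVEEP		protease	MMP	7		1587.81	++	MGRGHAR	783.91	-	LVHVEEP	821.90	-
10	EQVADIDGQYAMTR		protease	Caspase	7		1596.73	++	EQVADID	788.81	-	GQYAMTR	825.92	-
11	LEERPAVMTSPLYL		protease	MMP 2	7		1618.91	+++	LEERPAV	812.92	-	MTSPLYL	823.99	-
12	QFWSLAAPQRFGKK		protease	Tissue plasminogen activator, t-PA	7		1663.95	++	QFWSLAA	821.93	+	PQRFGKK	860.02	+
13	RRPKPQQFFGLMGK		protease	MMP 9	7		1690.05	++	RRPKPQQ	909.06	-	FFGLMGK	798.99	-
14	YEVHHQKLVFFAED		protease	MMP	7		1761.95	+	YEVHHQK	940.03	-	LVFFAED	839.92	-
15	RIRTQSFSLQE		kinase	Kinases AKT1, CAMK2		6	1364.53	++	RIRTQSpFSLQE	1444.43	+
16	ELQDDYEDLLE		kinase	Kinases SYK, LYN		6	1381.41	-	ELQDDYpEDLLE	1461.31	-
17	NKRRGSVPILR		kinase	Protein kinase A		6	1295.56	+++	NKRRGSpVPILR	1375.46	-
18	LLRGPSWDPFR		kinase	Kinases MAPKAPK-2, PKG1		6	1343.57	++	LLRGPSpWDPFR	1423.47	+
19	DADEYLIPQQG	phospho@5	phosphatase	PTP1B, TC-PTP, SHP-2		5	1327.00	+	DADEY*LIPQQG	1248.31
20	GDAEYAAKR	MCA@nterm;phospho@5;DNP@8	phosphatase	Protein Tyrosine Phosphatase		5	1530.55	+	MCA-GDAEY*AAK(DNP)R	1451.55	+
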