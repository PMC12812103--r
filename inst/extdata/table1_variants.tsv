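patient_id	family_id	gene	chrom	pos	ref	alt	hgvs_c	hgvs_p	consequence	clinvar	maf_nfe	cadd	sift	polyphen	revel	fathmm_cancer	spliceai	maxentscan_effect	coverage	call_quality	allele_fraction	zygosity
WI207-III.1	WI207	ATM	11	108331877	A	C	c.7630-2A>C	.	splice_canonical	P	1.441e-05	34.0	.	.	.	.	0.91	.	100	99	0.5	het
WI166-III.1	WI166	ATM	11	108332848	TA	GC	c.7875_7876delinsGC	p.(D2625_A2626delinsEP)	inframe_indel	LP/P	0	22.4	.	.	.	.	.	.	100	99	0.5	het
WI14-III.1	WI14	BRCA2	13	32319330	G	C	c.316+5G>C	.	splice_region	P	0	22.3	.	.	.	.	0.92	.	100	99	0.5	het
WI60-III.1	WI60	BRCA2	13	32336579	C	T	c.2224C>T	p.(Q742*)	stop_gain	P	0	33.0	.	.	.	.	.	.	100	99	0.5	het
WI226-III.1	WI226	BRCA2	13	32337185	A	T	c.2830A>T	p.(K944*)	stop_gain	P	3.390e-06	32.0	.	.	.	.	.	.	100	99	0.5	het
WI175-III.1	WI175	BRCA2	13	32338763	ATT	A	c.4409_4410del	p.(I1470Kfs*11)	frameshift	P	0	21.2	.	.	.	.	.	.	100	99	0.5	het
WI86-III.1	WI86	BRIP1	17	61859791	G	T	c.205+5G>T	.	splice_region	LP	0	24.2	.	.	.	.	0.85	.	100	99	0.5	het
WI04-III.1	WI04	CDKN2A	9	21971200	G	A	c.159G>A	p.(M53I)	missense	LP/P	0	27.1	D	B	0.724	-2.86	0.02	.	100	99	0.5	het
WI191-III.1	WI191	COL7A1	3	48570639	G	A	c.7344G>A	p.(V2448V)	splice_region	P	6.638e-05	22.8	.	.	.	.	0.63	.	100	99	0.5	het
WI165-III.1	WI165	EPCAM	2	47374035	C	T	c.412C>T	p.(R138*)	stop_gain	P	1.695e-06	42.0	.	.	.	.	.	.	100	99	0.5	het
WI50-III.1	WI50	FAH	15	80180230	G	A	c.1062+5G>A	.	splice_region	P	4.642e-04	23.5	.	.	.	.	0.78	.	100	99	0.5	het
WI209-III.1	WI209	FANCA	16	89746848	A	G	c.3391A>G	p.(T1131A)	missense	LP/P	1.614e-04	25.5	D	PoD	0.842	3.74	0.09	.	100	99	0.5	het
WI166-III.1	WI166	GBA1	1	155235843	A	G	c.1226A>G	p.(N409S)	missense	LP/P	1.728e-03	24.1	D	B	0.673	2.36	0.21	.	100	99	0.5	het
WI205-III.1	WI205	GBA1	1	155235843	A	G	c.1226A>G	p.(N409S)	missense	LP/P	1.728e-03	24.1	D	B	0.673	2.36	0.21	.	100	99	0.5	het
WI214-III.1	WI214	GBA1	1	155235843	A	G	c.1226A>G	p.(N409S)	missense	LP/P	1.728e-03	24.1	D	B	0.673	2.36	0.21	.	100	99	0.5	het
WI09-III.1	WI09	GBA1	1	155235195	G	A	c.1505G>A	p.(R502H)	missense	LP/P	3.391e-06	34.0	D	PrD	0.842	2.32	0.38	.	100	99	0.5	het
WI75-III.1	WI75	GJB2	13	20189117	T	A	c.465T>A	p.(Y155*)	stop_gain	P	8.474e-07	29.5	.	.	.	.	.	.	100	99	0.5	het
WI48-III.1	WI48	GJB2	13	20189473	G	A	c.109G>A	p.(V37I)	missense	P	8.816e-04	21.7	T	PrD	0.656	3.08	0.02	.	100	99	0.5	het
WI49-III.1	WI49	GJB2	13	20189473	G	A	c.109G>A	p.(V37I)	missense	P	8.816e-04	21.7	T	PrD	0.656	3.08	0.02	.	100	99	0.5	het
WI70-III.1	WI70	MUTYH	1	45332445	G	A	c.650G>A	p.(R217H)	missense	LP/P	6.695e-05	25.8	D	PrD	0.927	0.27	0.08	.	100	99	0.5	het
Fam003-III.1	Fam003	MYO7A	11	77184688	G	T	c.3476G>T	p.(G1159V)	missense	LP/P	5.355e-04	29.1	D	PrD	0.938	0.53	0.00	.	100	99	0.5	het
WI78-III.1	WI78	SAMHD1	20	36951576	C	G	c.68C>G	p.(S23*)	stop_gain	LP/P	2.542e-05	33.0	.	.	.	.	.	.	100	99	0.5	het
LI06-III.1	LI06	SDHA	5	223509	C	T	c.91C>T	p.(R31*)	stop_gain	LP/P	5.341e-04	34.0	.	.	.	.	.	.	100	99	0.5	het
WI87-III.1	WI87	SDHA	5	223509	C	T	c.91C>T	p.(R31*)	stop_gain	LP/P	5.341e-04	34.0	.	.	.	.	.	.	100	99	0.5	het
WI105-III.1	WI105	ATM	11	108245028	T	A	c.901+2T>A	.	splice_canonical	.	0	33.0	.	.	.	.	0.99	.	100	99	0.5	het
WI160-III.1	WI160	ATM	11	108365366	T	G	c.9029T>G	p.(L3010*)	stop_gain	.	0	42.0	.	.	.	.	.	.	100	99	0.5	het
WI191-III.1	WI191	BRCA2	13	32398608	A	GAATTATATCT	c.10095delinsGAATTATATCT	p.(S3366Nfs*4)	frameshift	C	0	24.2	.	.	.	.	.	.	100	99	0.5	het
WI72-III.1	WI72	ERCC5	13	102854319	C	T	c.412C>T	p.(R138*)	stop_gain	.	3.390e-06	36.0	.	.	.	.	.	.	100	99	0.5	het
WI53-III.1	WI53	KAT5	11	65718667	C	T	c.1342C>T	p.(R448*)	stop_gain	.	1.695e-06	37.0	.	.	.	.	.	.	100	99	0.5	het
WI222-III.1	WI222	NF2	22	29694776	C	T	c.1762C>T	p.(R588*)	stop_gain	VUS	6.780e-06	40.0	.	.	.	.	.	.	100	99	0.5	het
WI22-III.2	WI22	PCYT1A	3	196238789	C	T	c.1003C>T	p.(R335*)	stop_gain	VUS	1.028e-05	40.0	.	.	.	.	.	.	100	99	0.5	het
WI88-III.1	WI88	POLE	12	132687315	A	T	c.1A>T	p.(M1L)	start_loss	C	1.495e-04	21.9	D	B	0.257	3.37	0.01	.	100	99	0.5	het
WI183-III.1	WI183	SDHA	5	254390	C	G	c.1795-3C>G	.	splice_region	C	1.706e-06	24.1	.	.	.	.	0.85	.	100	99	0.5	het
WI48-III.1	WI48	TRPM1	15	31002524	AAGAC	A	c.4173_4176delAGAC	p.(D1392Lfs*11)	frameshift	VUS	1.669e-04	25.0	.	.	.	.	.	.	100	99	0.5	het
WI99-III.1	WI99	APC	5	112841473	C	T	c.5879C>T	p.(P1960L)	missense	C	5.341e-05	25.4	D	PrD	0.878	-5.39	0.00	.	100	99	0.5	het
WI89-III.1	WI89	APC	5	112842085	G	T	c.6491G>T	p.(G2164V)	missense	.	0	26.2	D	PrD	0.558	-4.46	0.00	.	100	99	0.5	het
WI37-III.1	WI37	ATM	11	108310267	A	G	c.5870A>G	p.(Y1957C)	missense	VUS	1.695e-06	26.9	D	PrD	0.602	-2.22	0.01	.	100	99	0.5	het
Fam004-III.1	Fam004	ATM	11	108326070	G	A	c.6820G>A	p.(A2274T)	missense	C	1.822e-04	27.5	D	PoD	0.524	-0.94	0.02	.	100	99	0.5	het
Fam002-II.2	Fam002	CDH1	16	68833300	C	T	c.2450C>T	p.(A817V)	missense	C	2.119e-05	27.2	D	PrD	0.574	-1.22	0.03	.	100	99	0.5	het
Fam002-III.1	Fam002	CDH1	16	68833300	C	T	c.2450C>T	p.(A817V)	missense	C	2.119e-05	27.2	D	PrD	0.574	-1.22	0.03	.	100	99	0.5	het
Fam002-III.2	Fam002	CDH1	16	68833300	C	T	c.2450C>T	p.(A817V)	missense	C	2.119e-05	27.2	D	PrD	0.574	-1.22	0.03	.	100	99	0.5	het
WI239-III.1	WI239	DICER1	14	95091226	A	G	c.5504A>G	p.(Y1835C)	missense	C	4.576e-05	28.8	D	PoD	0.736	-1.05	0.15	.	100	99	0.5	het
WI61-III.1	WI61	DICER1	14	95107993	T	G	c.2537T>G	p.(I846S)	missense	.	0	24.5	D	PoD	0.739	-1.63	0.07	.	100	99	0.5	het
WI201-III.1	WI201	EGFR	7	55154015	G	C	c.752G>C	p.(C251S)	missense	.	0	27.7	D	PrD	0.876	-3.48	0.02	.	100	99	0.5	het
WI177-II.1	WI177	EGFR	7	55174726	T	G	c.2189T>G	p.(L730R)	missense	C	2.204e-05	31.0	D	PrD	0.573	-1.9	0.02	.	100	99	0.5	het
WI33-III.1	WI33	EGFR	7	55200352	G	A	c.2885G>A	p.(R962H)	missense	C	2.229e-04	29.5	D	PoD	0.543	-1.97	0.07	.	100	99	0.5	het
WI153-III.1	WI153	ERCC2	19	45352511	G	A	c.2041G>A	p.(D681N)	missense	C	1.695e-05	24.9	D	PrD	0.898	-1.48	0.05	.	100	99	0.5	het
WI22-III.2	WI22	FLCN	17	17216464	A	G	c.1216A>G	p.(S406G)	missense	C	4.407e-05	25.3	D	PoD	0.672	-2.08	0.04	.	100	99	0.5	het
LI06-III.1	LI06	GATA2	3	128487002	G	T	c.30G>T	p.(W10C)	missense	C	1.881e-04	32.0	D	PoD	0.947	-1.25	0.00	.	100	99	0.5	het
WI169-II.2	WI169	HMBS	11	119088642	G	A	c.95G>A	p.(R32H)	missense	VUS	1.696e-06	29.2	D	PrD	0.885	.	0.06	.	100	99	0.5	het
WI11-III.1	WI11	PMS2	7	5992044	T	C	c.917T>C	p.(V306A)	missense	VUS	1.916e-05	27.6	D	PrD	0.824	-1.66	0.00	.	100	99	0.5	het
WI103-III.1	WI103	PMS2	7	5995563	A	T	c.874A>T	p.(I292F)	missense	VUS	2.543e-06	25.7	D	PrD	0.866	-1.88	0.06	.	100	99	0.5	het
WI51-III.1	WI51	TFAP2E	1	35590037	C	T	c.893C>T	p.(S298L)	missense	VUS	8.984e-05	28.3	D	PoD	0.922	-1.28	0.01	.	100	99	0.5	het
WI236-III.1	WI236	TP53	17	7675220	A	G	c.392A>G	p.(N131S)	missense	VUS	8.475e-07	27.0	D	PrD	0.859	-9.14	0.00	.	100	99	0.5	het
WI122-III.1	WI122	CTNND1	11	57814325	C	T	c.2653C>T	p.(R885W)	missense	VUS	1.867e-05	32.0	D	PoD	0.414	2.28	0.12	.	100	99	0.5	het
WI163-III.1	WI163	DIS3L2	2	232136590	G	A	c.821G>A	p.(R274Q)	missense	VUS	0	31.0	D	PrD	0.497	2.45	0.03	.	100	99	0.5	het
WI126-II.2	WI126	ERCC3	2	127286825	T	G	c.1220T>G	p.(I407S)	missense	.	0	30.0	D	PrD	0.710	1.87	0.00	.	100	99	0.5	het
WI106-III.1	WI106	IFIH1	2	162277667	C	T	c.1792C>T	p.(R598C)	missense	VUS	3.148e-05	32.0	D	PrD	0.556	2.27	0.00	.	100	99	0.5	het
Fam016-III.1	Fam016	POLE	12	132657402	C	T	c.3406C>T	p.(R1136W)	missense	VUS	4.237e-06	30.0	D	PrD	0.598	0.57	0.00	.	100	99	0.5	het
WI89-III.1	WI89	SLC4A7	3	27394756	A	G	c.2879A>G	p.(Y960C)	missense	.	4.238e-06	32.0	D	PrD	0.939	3.01	0.00	.	100	99	0.5	het
WI145-III.1	WI145	SLC25A13	7	96189581	G	A	c.848G>A	p.(G283E)	missense	VUS	9.086e-05	33.0	D	B	0.709	3.42	0.72	.	100	99	0.5	het
WI08-III.1	WI08	WDR7	18	56816031	C	T	c.3191C>T	p.(P1064L)	missense	VUS	5.124e-06	33.0	D	PoD	0.242	0.01	0.00	.	100	99	0.5	het
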