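# SujuNPV (Sucra jujuba nucleopolyhedrovirus) genome annotation, GenBank KJ676450;
# transcribed from the published annotation table (131 ORFs + 7 homologous regions).
orf	name	motif	start	end	length_aa	strand	pos_AcMNPV	pos_HearNPV	pos_CpGV	pos_NeleNPV	pos_CuniNPV	id_AcMNPV	id_HearNPV	id_CpGV	id_NeleNPV	id_CuniNPV
1	polyhedrin	E	1	741	246	+	8	1	1	1		86.5	88.2	53.7	45.1	
2	orf1629	L	774	2474	566	-	9	2	2			14.9	19.6	17.2		
3	pk-1		2467	3270	267	+	10	3	3			32.6	44.6	30.3		
4	hoar	E	3313	5259	506	-		4					15			
5	orf5		5663	6724	353	+										
6	pif-5	L	6962	8059	365	+	148	15	18	23	102	53.4	53.7	45.1	37.5	19.7
7	bro-1	L	8122	8466	114	+		59					23.7			
8	cg30-2		8570	9388	272	+	88	77				15.5	12.1			
9	p10	L	9436	9696	86	-	137	21	22			27.4	35.7	31		
10	p26-1	E,L	9747	10604	285	-	136	22				34.6	43.8			
	hr1		10666	11269												
11	ac29		11438	11656	72	+	29	23				25.4	40.3			
12	lef-6	L	11762	12508	248	-	28	24	80			19.7	26.2	16.8		
13	dbp-2		12532	13464	310	-	25	25	81	14		18.1	23.9	14.1	14.8	
	hr2		13546	14517												
14	orf14		13638	13889	83	+										
15	p74	L	14521	16479	652	-	138	20	60	47	74	57.8	54.4	39.4	38.9	32.8
	hr3		16580	17170												
16	me-53	E	17219	18349	376	-	139	16-17	143			16.8	22.6	17.2		
17	ie-0	E,L	18698	19495	265	+	141	8				24.5	27.5			
18	p49	L	19595	21028	477	+	142	9	15	60	30	44.4	55.8	26.3	19.2	6.3
19	odv-e18	L	21058	21324	88	+	143	10	14	62	31	61.3	51.9	38.1	18.8	7.9
20	odv-ec27	L	21428	22306	292	+	144	11	97	63	32	45.9	52.1	22.2	21	15.3
21	chtb	L	22336	22614	92	+	145	12	9	64		45.5	44.6	31.5	27.2	
22	ep23	L	22639	23262	207	-	146	13	8			29.4	25.6	19.3		
23	ie-1	E	23325	25439	704	+	147	14	7			24.9	27.2	11.7		
24	ac34	L	25586	26134	182	-	34	27				23.6	50			
25	orf25	E	26224	26802	192	-										
26	ubiquitin	L	26988	27254	88	+	35	28	54			74	72.3	68.2		
27	39k		27529	28428	299	-	36	31	57			33.1	35.5	5.8		
28	lef-11		28430	28786	118	-	37	32	58			33	30.5	27.1		
29	bv-e31	L	28711	29433	240	-	38	33	69			53.7	48.3	39.5		
30	dbp-1	E,L	29783	30712	309	+	25	25	81			24.9	34	12.4		
31	p47		30827	32011	394	-	40	35	68	46	73	53.6	50.8	45.2	25.2	14
32	lef-12	E	32272	33114	280	-	41	36				30.9	29.6			
33	lef-8		33321	36038	905	-	50	38	131	78	26	63	68.9	49.1	30.5	18.3
34	orf34		33504	34118	204	+	34	orf34								
35	djbp		36078	37316	412	+	51	39				15.4	20.1			
	hr4		37323	37964												
36	iap-1	L	38038	38844	268	-	27	103	17	11	17	24.3	23.1	24.3	12.7	3.1
37	ac52		39221	39895	224	-	52	42				19.5	30.6			
38	ac53	L	39855	40328	157	+	53	43	134	77	28	46	52.2	17.3	12.1	8.9
39	orf39	L	40332	41459	375	-		44					17.3			
40	orf40	L	41473	41709	78	-										
41	vp1054	L	41760	42869	369	+	54	47	138	83	8	39.7	47.9	30.1	18.8	18.5
42	ac55		43039	43242	67	+	55	48				35.8	56.7			
43	ac56	L	43184	43534	116	+	56	49				11.9	32.8			
44	ac57	E,L	43717	44208	163	+	57	50				35.4	38.7			
45	chaB	E,L	44279	44800	173	-	59	51				37.7	34.4			
46	chaB	L	44876	45145	89	-	60	52				41.4	39.8			
47	bro-2	L	45281	45697	138	-		60					27.5			
48	fp/25k	L	45905	46549	214	-	61	53	118			51.9	56.1	28		
49	lef-9		46687	48216	509	+	62	55	117	37	59	66.2	66.6	52.3	34	18.9
50	dna ligase		48547	50361	604	+			120					23.5		
51	bro-3		50436	51428	330	-	2	105				36	13.3			
52	gp37	E	51534	52391	285	-	64	58	13			45.3	55.6	41.4		
53	orf53		52471	53133	220	+										
54	chitinase	L	53319	55037	572	-	126	41	10			68.8	63.7	57.3		
55	v-cath	L	55144	56136	330	+	127	56	11			66.6	47	42.4		
56	p26-2	E	56200	56919	239	-	136	22				17.2	15.9			
57	helicase-2		57035	58390	451	-			126					27.5		
58	ac150	L	58435	58752	105	-	150	12	79			25.3	21.7	25.7		
59	iap-2	E	58756	59682	308	-	71	62	17			28.9	35.2	16		
60	pif-6		59711	60088	125	-	68	64	114	38	58	35.2	44	24	21.6	16
61	lef-3		60087	61340	417	+	67	65	113			17.9	23.7	4.5		
62	desmoplakin	L	61434	64043	869	-	66	66	112	21	92	17.6	17.1	12.3	11.7	10.7
63	dna polymerase		64042	67248	1068	+	65	67	111	20	91	44.5	51.6	30.9	24.3	16.5
64	ac75	L	67287	67679	130	-	75	69	108			20	34.6	10.8		
65	ac76	L	67774	68031	85	-	76	70	107			41.7	65.9	35.7		
66	vlf-1	L	68185	69354	389	-	77	71	106	42	18	67.5	69.4	28.6	25.1	18.2
67	ac78	L	69378	69710	110	-	78	72	105	43	34	33	45.5	13.6	21.3	16.7
68	gp41	L	69758	70963	401	-	80	73	104	44	33	43.1	53.4	28.4	26.3	11.5
69	ac81		70932	71621	229	-	81	74	103	45	106	48.9	52.4	41.9	33.1	16.1
70	tlp-20	L	71515	72237	240	-	82	75	102			26.7	33.8	11.6		
71	vp91	L	72206	74731	841	+	83	76	101	82	35	37.6	42.8	21.8	23.4	22.3
72	cg30	E	74792	75739	315	-	88	77				19.7	18.7			
73	vp39	L	75861	76835	324	-	89	78	96	88	24	36.4	42	22.5	19	14.5
74	lef-4		76834	78264	476	+	90	79	95	59	96	45.7	45.1	30.3	25	13.7
75	orf75	L	78301	78726	141	-		77					9.9			
76	p33	E,L	78822	79580	252	-	92	80	93	16	14	50.4	57.9	35.1	19.4	19
77	p18	L	79579	80055	158	+	93	81	92	17	13	52.5	62	31	17.1	4.8
78	odv-e25	L	80057	80728	223	+	94	82	91	18	15	39	59.2	48.8	13	11.2
79	helicase-1	L	80777	84505	1242	-	95	84	90	58	89	41	46.9	22.5	17.4	11.1
80	pif-4		84459	84980	173	+	96	85	89	57	90	50.3	57.8	35.4	26.2	25.4
81	38k	L	85007	85927	306	-	98	86	88	56	87	42.8	50.3	39.5	27.2	24.8
82	lef-5	L	85811	86662	283	+	99	87	87	55	88	46.8	54.4	38	27.2	7.9
83	p6.9		86739	86999	86	+	100	88	86	28	23	7.3	8.1	4.1	8.1	13.8
84	p40	E,L	87012	88154	380	-	101	89	85	29	22	40.2	41.2	17.6	13.7	7.6
85	p12	L	88194	88553	119	-	102	90	84			21.8	20.2	13.8		
86	p48/p45	E,L	88540	89727	395	-	103	91	83	31	55	42.4	47.5	31.9	15.6	6
87	vp80		89820	92120	766	+	104	92				12	17.2			
88	ac110		92160	92334	57	+	110	93	53			28.6	40.4	25		
89	odv-ec43	L	92343	93482	379	+	109	94	55	67	69	48.3	58.4	30.4	15.3	10.3
90	ac108	L	93532	93789	85	+	108	95				29.4	41.2			
91	orf91		93807	94313	168	-										
92	endonuclease	L	94403	94762	119	+	79		65			24		26.6		
93	ac112		94746	95765	339	+	112					31				
	hr5		95796	96554												
94	nrk1		96753	97811	352	+	33		16			26.4		29.6		
95	p43	E	97850	99010	386	-	39					18.2				
96	iap-3		99009	99479	156	+	27	103	94			23.1	24.4	27.6		
97	ac106	E,L	99518	100228	236	-	106	101	52	32		50.8	49.6	25.4	16.5	
98	parg	L	100286	101974	562	-		100					16.7			
99	orf99		102055	102522	155	-		99					17.8			
100	pif-3	L	102512	103135	207	-	115	98	35	66	46	44.1	47.2	35.7	28.5	31.5
101	orf101		103207	103581	124	-										
102	sod	L	103683	104159	158	+	31	106	59			60.9	62.7	46.2		
103	ac117		104202	104513	103	+	117	110				22.1	39.8			
104	calyx/pep	L	104559	105578	339	-	131	120	22	50		22.6	35.7	12.1	12.1	
105	orf105		105634	106980	448	+										
106	orf106		107008	107532	174	-										
107	orf107	L	108086	108496	136	+		68					13.2			
	hr6		108513	109329												
108	p24	L	109521	110312	263	+	129	118	71			37.9	52	24.1		
109	orf109	L	110450	110818	122	+										
110	lef-2		110826	111515	229	+	6	117	41	54	25	36.2	36.7	18.7	15.4	11.6
111	pkip	L	111630	112145	171	+	24	130				13	29.6			
112	orf112		112189	112524	111	-										
113	pif-2	L	112615	113769	384	+	22	132	48	52	38	60.2	68.1	50.3	44.3	46.4
114	ac111		113827	114033	68	-	111	116				55.2	30.9			
	hr7		114159	114766												
115	F	E,L	114888	116945	685	-	23	133	31		104	14.2	37.8	24.5		15.3
116	orf116		117225	120083	952	+		129					24.6			
117	ac17		120196	120909	237	-	17	128				16.5	29.1			
118	orf118	E,L	120959	121600	213	-		127					21.4			
119	egt	E	121812	123353	513	-	15	126	141			45.1	51.7	35.5		
120	orf120	L	123560	123916	118	-										
121	lef-1		124016	124717	233	+	14	124	74	65	45	35.6	42.1	33.9	28.4	21.5
122	38.7k		124783	126009	408	+	13	123	73			22.9	31.9	13.1		
123	ac19	L	126065	126508	147	-	19	115				21.3	23.3			
124	orf124	L	126507	127745	412	+										
125	alk-exo	L	127807	129066	419	+	133	114	125	33	54	36.3	40.3	32.4	24.4	21.5
126	orf126	L	129111	129875	254	-										
127	fgf		130158	131180	340	+	32	113	123			23.8	19.6	9.1		
128	orf128		131201	131440	79	-		112								
129	pif-1	L	131447	133045	532	-	119	111	75	76	29	52.1	46.4	33.3	29.1	26
130	bro-4		133123	133962	279	-	2					13.6				
131	dna photolyase	E	134303	135796	497	+										
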