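# SujuNPV conservation tiers, transcribed from the published gene-function classification:
# 37 baculovirus core genes, 24 lepidopteran-baculovirus-conserved genes, 5 SujuNPV-unique genes.
tier	orf	name
core	6	pif-5
core	15	p74
core	18	p49
core	19	odv-e18
core	20	odv-ec27
core	31	p47
core	33	lef-8
core	38	ac53
core	41	vp1054
core	49	lef-9
core	60	pif-6
core	62	desmoplakin
core	63	dna polymerase
core	66	vlf-1
core	67	ac78
core	68	gp41
core	69	ac81
core	71	vp91
core	73	vp39
core	74	lef-4
core	76	p33
core	77	p18
core	78	odv-e25
core	79	helicase-1
core	80	pif-4
core	81	38k
core	82	lef-5
core	83	p6.9
core	84	p40
core	86	p48/p45
core	89	odv-ec43
core	100	pif-3
core	110	lef-2
core	113	pif-2
core	121	lef-1
core	125	alk-exo
core	129	pif-1
lepidopteran	1	polyhedrin
lepidopteran	2	orf1629
lepidopteran	3	pk-1
lepidopteran	12	lef-6
lepidopteran	16	me-53
lepidopteran	21	chtb
lepidopteran	22	ep23
lepidopteran	23	ie-1
lepidopteran	27	39k
lepidopteran	28	lef-11
lepidopteran	29	bv-e31
lepidopteran	30	dbp-1
lepidopteran	48	fp/25k
lepidopteran	61	lef-3
lepidopteran	64	ac75
lepidopteran	65	ac76
lepidopteran	70	tlp-20
lepidopteran	85	p12
lepidopteran	88	ac110
lepidopteran	97	ac106
lepidopteran	108	p24
lepidopteran	115	F
lepidopteran	122	38.7k
lepidopteran	127	fgf
unique	5	orf5
unique	14	orf14
unique	25	orf25
unique	53	orf53
unique	106	orf106
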