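chrom	start	end	gene	oa_vs_con	eat_vs_oa	ecb_vs_oa	region	n_cpgs	association
17	58564101	58564200	APPBP2	Hypermethylation	Hypomethylation	-	LINE	4	NONE
1	3414951	3415050	MEGF6	Hypermethylation	-	Hypomethylation	Exon	8	NONE
7	12717651	12717800	ARL4A	Hypermethylation	-	Hypomethylation	SINE	9	NONE
16	8941701	8941800	PMM2	Hypermethylation	Hypomethylation	-	3'UTR	5	NONE
5	78985701	78985800	CMYA5	Hypermethylation	Hypomethylation	-	TSS	14	Hypertension, cardiomyopathies
16	57508751	57508850	DOK4	Hypermethylation	Hypomethylation	-	Exon	6	Immune response
14	34992451	34992600	EAPP	Hypermethylation	Hypomethylation	-	Intron	9	NONE
10	131767451	131767600	EBF3	Hypermethylation	Hypomethylation	Hypomethylation	CpG	16	NONE
20	57875301	57875450	EDN3	Hypermethylation	-	Hypomethylation	TSS	16	Cardiovascular disease, hypertension, stroke
1	161432051	161432300	FCGR2A	Hypermethylation	Hypomethylation	-	Intergenic	34	Stroke, ulcerative colitis
4	153788351	153788450	ARFIP1	Hypermethylation	Hypomethylation	-	Intron	8	NONE
20	57465401	57465500	GNAS	Hypermethylation	-	Hypomethylation	TSS	16	Hypertension, cardiovascular disease, obesity, diabetes, atherosclerosis
2	11733051	11733150	GREB1	Hypermethylation	-	Hypomethylation	TTS	7	NONE
16	27781251	27781350	KIAA0556	Hypermethylation	Hypomethylation	-	Exon	3	NONE
4	84320351	84320450	HELQ	Hypermethylation	Hypomethylation	-	LINE	4	NONE
2	172771151	172771250	HAT1	Hypermethylation	Hypomethylation	-	Intergenic	2	Asthma
7	138661001	138661200	KIAA1549	Hypermethylation	Hypomethylation	-	Intron	7	NONE
1	220943251	220943350	MARC2	Hypermethylation	-	Hypomethylation	Intron	3	NONE
1	193109701	193109800	CDC73	Hypermethylation	Hypomethylation	-	Intron	3	Hyperlipidemias, myocardial infarction
16	56669401	56669500	MT1JP	Hypermethylation	Hypomethylation	-	TSS	16	NONE
2	233863451	233863550	NGEF	Hypermethylation	Hypomethylation	-	Intron	3	NONE
20	21503451	21503550	NKX2-2	Hypermethylation	-	Hypomethylation	CpGIntergenic	8	Diabetes, obesity
20	21503151	21503300	NKX2-2	Hypermethylation	Hypomethylation	-	CpGIntergenic	26	Diabetes, obesity
15	53079651	53079750	ONECUT1	Hypermethylation	Hypomethylation	-	Intergenic	6	Diabetes
6	107684801	107684900	PDSS2	Hypermethylation	-	Hypomethylation	LTR	5	NONE
2	65928451	65928550	SPRED2	Hypermethylation	Hypomethylation	-	Intergenic	5	Arthritis
2	120000901	120001000	STEAP3	Hypermethylation	Hypomethylation	-	IntronTTS	2	NONE
2	120000951	120001050	STEAP3	Hypermethylation	Hypomethylation	-	IntronTTS	2	NONE
2	101747801	101747900	TBC1D8	Hypermethylation	Hypomethylation	-	SINE	5	NONE
1	32696701	32696800	EIF3I	Hypermethylation	-	Hypomethylation	TTS	7	NONE
6	169977751	169977900	WDR27	Hypermethylation	Hypomethylation	Hypomethylation	CpG	15	Diabetes
2	223731451	223731500	ACSL3	Hypomethylation	Hypermethylation	-	Intron	3	Hepatic lipogenesis, insulin sensitivity, hepatic steatosis
4	41218351	41218550	APBB2	Hypomethylation	Hypermethylation	-	Intergenic	21	Obesity, diabetes
11	27722001	27722150	BDNF	Hypomethylation	Hypermethylation	-	TSS	20	Obesity, stroke, diabetes, coronary artery disease
22	19799851	19800000	GNB1L	Hypomethylation	Hypermethylation	-	Exon	7	NONE
17	80278851	80279000	SECTM1	Hypomethylation	Hypermethylation	-	TTS	14	NONE
5	30346051	30346200	CDH6	Hypomethylation	Hypermethylation	-	LTR	11	NONE
19	59093201	59093300	CENPBD1P1	Hypomethylation	Hypermethylation	-	Non-coding	8	NONE
17	16258051	16258150	CENPV	Hypomethylation	Hypermethylation	-	Simple repeats	5	NONE
8	61626901	61627050	CHD7	Hypomethylation	Hypermethylation	-	CpG	11	NONE
9	11101	11250	DDX11L5	Hypomethylation	Hypermethylation	-	TSS	19	NONE
16	70323601	70323750	DDX19B	Hypomethylation	Hypermethylation	-	TSS	9	NONE
4	3465101	3465250	DOK7	Hypomethylation	Hypermethylation	-	CpG	19	Lipid metabolism
18	48533301	48533400	ELAC1/SMAD4	Hypomethylation	Hypermethylation	-	LTR	3	Cardiovascular disease, hypertension, diabetes
2	96066001	96066100	FAHD2A	Hypomethylation	Hypermethylation	-	LTR	4	NONE
6	32099051	32099150	FKBPL	Hypomethylation	Hypermethylation	-	Intergenic	9	Angiogenesis
15	74340851	74341000	PML	Hypomethylation	Hypermethylation	-	TTS	8	Hypertension, stroke, coronary artery disease
1	156717001	156717100	HDGF	Hypomethylation	Hypermethylation	-	Simple repeats	6	Hypertension
3	193922151	193922250	LINC002036	Hypomethylation	-	Hypermethylation	CpG	14	NONE
4	7864101	7864200	AFAP1	Hypomethylation	Hypermethylation	-	Intron	5	NONE
2	91634801	91634950	LOC654342	Hypomethylation	Hypermethylation	Hypermethylation	CpG	19	NONE
7	150105001	150105100	LOC728743	Hypomethylation	Hypermethylation	-	Non-coding	21	NONE
X	27827551	27827700	MAGEB10	Hypomethylation	Hypermethylation	-	LTR	18	NONE
X	35517551	35517700	MAGEB16	Hypomethylation	Hypermethylation	-	LTR	13	NONE
13	113705001	113705100	MCF2L	Hypomethylation	Hypermethylation	-	Intron	10	Cardiovascular disease, atherosclerosis
5	126626501	126626600	MEGF10	Hypomethylation	Hypermethylation	-	TSS	8	NONE
22	39853201	39853300	MGAT3	Hypomethylation	-	Hypermethylation	TSS	22	NONE
16	67235901	67236050	ELMO3	Hypomethylation	-	Hypermethylation	TTS	9	NONE
19	45954101	45954250	FOSB	Hypomethylation	Hypermethylation	-	Intergenic	22	NONE
20	39795151	39795250	PLCG1	Hypomethylation	Hypermethylation	-	Exon	5	NONE
4	4858701	4858850	MSX1	Hypomethylation	Hypermethylation	-	Intergenic	15	NONE
7	559501	559600	PDGFA	Hypomethylation	Hypermethylation	-	TSS	12	Asthma
10	6242601	6242700	PFKFB3	Hypomethylation	Hypermethylation	-	Simple repeats	3	Insulin resistance, diabetes, obesity, inflammation
1	249239551	249239700	PGBD2	Hypomethylation	Hypermethylation	Hypermethylation	Intergenic	7	NONE
7	102213151	102213250	POLR2J3	Hypomethylation	Hypermethylation	-	TSS	11	NONE
14	92044551	92044650	CATSPERB/SMEK1	Hypomethylation	Hypermethylation	-	LTR	3	NONE
17	42015751	42015900	PPY	Hypomethylation	Hypermethylation	-	Simple repeats	12	Diabetes, obesity
10	52834351	52834450	PRKG1	Hypomethylation	Hypermethylation	Hypermethylation	Exon	6	Cardiovascular disease, hypertension, stroke, diabetes
11	62192201	62192350	SCGB1A1	Hypomethylation	Hypermethylation	-	Intergenic	9	Hypertension, diabetes, stroke, asthma
4	19415401	19415550	SLIT2	Hypomethylation	Hypermethylation	-	Simple repeats	8	Hypertension, diabetes, obesity, stroke
2	220313351	220313450	SPEG	Hypomethylation	-	Hypermethylation	Exon	15	Cardiovascular disease
7	98384201	98384350	TMEM130	Hypomethylation	Hypermethylation	-	LTR	4	NONE
14	38067501	38067550	TTC6	Hypomethylation	-	Hypermethylation	CpG	3	NONE
7	150105051	150105150	LOC728743	Hypomethylation	-	Hypermethylation	Non-coding	15	NONE
1	244354201	244354300	ZBTB18	Hypomethylation	Hypermethylation	-	Intergenic	3	NONE
8	106330701	106330850	ZFPM2	Hypomethylation	Hypermethylation	-	TSS	20	NONE
16	88476201	88476350	ZNF469	Hypomethylation	Hypermethylation	-	Intergenic	7	NONE
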