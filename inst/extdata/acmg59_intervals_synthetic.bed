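1	9000000	9000300	CACNA1S
1	9001000	9001450	CACNA1S
1	9002000	9002600	CACNA1S
1	19000000	19000300	LMNA
1	19001000	19001450	LMNA
1	19002000	19002600	LMNA
1	24000000	24000300	MUTYH
1	24001000	24001450	MUTYH
1	24002000	24002600	MUTYH
1	32000000	32000300	PCSK9
1	32001000	32001450	PCSK9
1	32002000	32002600	PCSK9
1	40000000	40000300	RYR2
1	40001000	40001450	RYR2
1	40002000	40002600	RYR2
1	43000000	43000300	SDHB
1	43001000	43001450	SDHB
1	43002000	43002600	SDHB
1	44000000	44000300	SDHC
1	44001000	44001450	SDHC
1	44002000	44002600	SDHC
1	53000000	53000300	TNNT2
1	53001000	53001450	TNNT2
1	53002000	53002600	TNNT2
10	1000000	1000300	ACTA2
10	1001000	1001450	ACTA2
10	1002000	1002600	ACTA2
10	6000000	6000300	BMPR1A
10	6001000	6001450	BMPR1A
10	6002000	6002600	BMPR1A
10	36000000	36000300	PTEN
10	36001000	36001450	PTEN
10	36002000	36002600	PTEN
10	38000000	38000300	RET
10	38001000	38001450	RET
10	38002000	38002600	RET
11	17000000	17000300	KCNQ1
11	17001000	17001450	KCNQ1
11	17002000	17002600	KCNQ1
11	20000000	20000300	MEN1
11	20001000	20001450	MEN1
11	20002000	20002600	MEN1
11	25000000	25000300	MYBPC3
11	25001000	25001450	MYBPC3
11	25002000	25002600	MYBPC3
11	42000000	42000300	SDHAF2
11	42001000	42001450	SDHAF2
11	42002000	42002600	SDHAF2
11	45000000	45000300	SDHD
11	45001000	45001450	SDHD
11	45002000	45002600	SDHD
11	59000000	59000300	WT1
11	59001000	59001450	WT1
11	59002000	59002600	WT1
12	28000000	28000300	MYL2
12	28001000	28001450	MYL2
12	28002000	28002600	MYL2
12	33000000	33000300	PKP2
12	33001000	33001450	PKP2
12	33002000	33002600	PKP2
13	5000000	5000300	ATP7B
13	5001000	5001450	ATP7B
13	5002000	5002600	ATP7B
13	8000000	8000300	BRCA2
13	8001000	8001450	BRCA2
13	8002000	8002600	BRCA2
13	37000000	37000300	RB1
13	37001000	37001450	RB1
13	37002000	37002600	RB1
14	27000000	27000300	MYH7
14	27001000	27001450	MYH7
14	27002000	27002600	MYH7
15	2000000	2000300	ACTC1
15	2001000	2001450	ACTC1
15	2002000	2002600	ACTC1
15	14000000	14000300	FBN1
15	14001000	14001450	FBN1
15	14002000	14002600	FBN1
15	46000000	46000300	SMAD3
15	46001000	46001450	SMAD3
15	46002000	46002600	SMAD3
15	55000000	55000300	TPM1
15	55001000	55001450	TPM1
15	55002000	55002600	TPM1
16	26000000	26000300	MYH11
16	26001000	26001450	MYH11
16	26002000	26002600	MYH11
16	57000000	57000300	TSC2
16	57001000	57001450	TSC2
16	57002000	57002600	TSC2
17	7000000	7000300	BRCA1
17	7001000	7001450	BRCA1
17	7002000	7002600	BRCA1
17	54000000	54000300	TP53
17	54001000	54001450	TP53
17	54002000	54002600	TP53
18	11000000	11000300	DSC2
18	11001000	11001450	DSC2
18	11002000	11002600	DSC2
18	12000000	12000300	DSG2
18	12001000	12001450	DSG2
18	12002000	12002600	DSG2
18	47000000	47000300	SMAD4
18	47001000	47001450	SMAD4
18	47002000	47002600	SMAD4
19	18000000	18000300	LDLR
19	18001000	18001450	LDLR
19	18002000	18002600	LDLR
19	39000000	39000300	RYR1
19	39001000	39001450	RYR1
19	39002000	39002600	RYR1
19	48000000	48000300	STK11
19	48001000	48001450	STK11
19	48002000	48002600	STK11
19	52000000	52000300	TNNI3
19	52001000	52001450	TNNI3
19	52002000	52002600	TNNI3
2	4000000	4000300	APOB
2	4001000	4001450	APOB
2	4002000	4002600	APOB
2	10000000	10000300	COL3A1
2	10001000	10001450	COL3A1
2	10002000	10002600	COL3A1
2	22000000	22000300	MSH2
2	22001000	22001450	MSH2
2	22002000	22002600	MSH2
2	23000000	23000300	MSH6
2	23001000	23001450	MSH6
2	23002000	23002600	MSH6
22	30000000	30000300	NF2
22	30001000	30001450	NF2
22	30002000	30002600	NF2
3	21000000	21000300	MLH1
3	21001000	21001450	MLH1
3	21002000	21002600	MLH1
3	29000000	29000300	MYL3
3	29001000	29001450	MYL3
3	29002000	29002600	MYL3
3	41000000	41000300	SCN5A
3	41001000	41001450	SCN5A
3	41002000	41002600	SCN5A
3	50000000	50000300	TGFBR2
3	50001000	50001450	TGFBR2
3	50002000	50002600	TGFBR2
3	51000000	51000300	TMEM43
3	51001000	51001450	TMEM43
3	51002000	51002600	TMEM43
3	58000000	58000300	VHL
3	58001000	58001450	VHL
3	58002000	58002600	VHL
5	3000000	3000300	APC
5	3001000	3001450	APC
5	3002000	3002600	APC
6	13000000	13000300	DSP
6	13001000	13001450	DSP
6	13002000	13002600	DSP
7	16000000	16000300	KCNH2
7	16001000	16001450	KCNH2
7	16002000	16002600	KCNH2
7	34000000	34000300	PMS2
7	34001000	34001450	PMS2
7	34002000	34002600	PMS2
7	35000000	35000300	PRKAG2
7	35001000	35001450	PRKAG2
7	35002000	35002600	PRKAG2
9	49000000	49000300	TGFBR1
9	49001000	49001450	TGFBR1
9	49002000	49002600	TGFBR1
9	56000000	56000300	TSC1
9	56001000	56001450	TSC1
9	56002000	56002600	TSC1
X	15000000	15000300	GLA
X	15001000	15001450	GLA
X	15002000	15002600	GLA
X	31000000	31000300	OTC
X	31001000	31001450	OTC
X	31002000	31002600	OTC
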