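accession	gene	description	sc_ref	abun_ref	sc_cmp	abun_cmp	sc_control	abun_control	nsaf_ratio_control	expression_control
P00352	ALDH1A1	Retinal dehydrogenase 1	26.3	M	2.7	VL	0.0	-	0.00	Absent in CG
Q6PEW0	PRSS54	Inactive serine protease 54	18.0	L	4.7	VL	0.0	-	0.00	Absent in CG
Q76KD6	SPATC1	Speriolin	8.3	L	2.3	VL	0.0	-	0.00	Absent in CG
Q9HAE3	EFCAB1	EF-hand calcium-binding domain-containing protein 1	9.3	L	3.3	VL	0.0	-	0.00	Absent in CG
O43242	PSMD3	26S proteasome non-ATPase regulatory subunit 3	33.7	M	78.3	M	0.0	-	0.00	Absent in CG
P23396	RPS3	40S ribosomal protein S3	24.7	M	60.0	M	0.0	-	0.00	Absent in CG
Q9NZM1-3	MYOF	Isoform 3 of Myoferlin	21.3	M	55.3	M	0.0	-	0.00	Absent in CG
Q96RQ1	ERGIC2	Endoplasmic reticulum-Golgi intermediate compartment protein 2	8.3	L	23.0	M	0.0	-	0.00	Absent in CG
Q8IYV9	IZUMO1	Izumo sperm-egg fusion protein 1	9.0	L	28.7	M	0.0	-	0.00	Absent in CG
Q04609	FOLH1	Glutamate carboxypeptidase 2	27.0	M	96.3	H	0.0	-	0.00	Absent in CG
Q8IY17-4	PNPLA6	Isoform 4 of Neuropathy target esterase	3.7	VL	14.0	L	0.0	-	0.00	Absent in CG
P62277	RPS13	40S ribosomal protein S13	5.3	VL	20.7	M	0.0	-	0.00	Absent in CG
Q13093	PLA2G7	Platelet-activating factor acetylhydrolase	5.3	VL	22.7	M	0.0	-	0.00	Absent in CG
O43653	PSCA	Prostate stem cell antigen	1.7	VL	14.3	L	0.0	-	0.00	Absent in CG
Q96M98-2	PACRG	Isoform 2 of Parkin coregulated gene protein	1.3	VL	21.0	M	0.0	-	0.00	Absent in CG
P46777	RPL5	60S ribosomal protein L5	5.7	VL	24.7	M	1.3	M	0.36	UE
P15289	ARSA	Arylsulfatase A	34.0	M	1.7	VL	4.7	VL	0.20	UE
P02788	LTF	Lactotransferrin	2486.7	H	1299.0	H	424.3	H	0.24	UE
P14314	PRKCSH	Glucosidase 2 subunit beta	123.0	H	65.0	M	33.7	M	0.39	UE
P27797	CALR	Calreticulin	271.7	H	175.0	H	123.0	H	0.65	UE
P14625	HSP90B1	Endoplasmin	987.0	H	660.3	H	73.3	M	0.11	UE
P05023-4	ATP1A1	Isoform 4 of Sodium/potassium-transporting ATPase subunit alpha-1	98.7	H	181.3	H	27.3	M	0.39	UE
O95202	LETM1	Mitochondrial proton/calcium exchanger protein	29.0	M	65.7	M	9.0	L	0.46	UE
Q9Y4W6	AFG3L2	AFG3-like protein 2	15.3	L	40.7	M	0.7	VL	0.06	UE
P11234	RALB	Ras-related protein Ral-B	9.0	L	22.0	M	62.0	M	10.12	OE
O43707	ACTN4	Alpha-actinin-4	44.7	M	23.3	L	52.3	M	1.73	OE
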