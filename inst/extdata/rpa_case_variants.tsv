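gene	subset	genomic_position	sample_id	diagnosis	domain	hgvs_c	hgvs_p	ancestry	af	ancestry_af	cadd	revel	acmg	ddg
RPA1	HEM	1747265	SJBALL032225	BALL	F	c.A136G	p.M46V	AMR	0.0013%	0.0029%	22.2	0.28	VUS	unavailable
RPA1	HEM	1747266	SJALL041240	BALL	F	c.T137C	p.M46T	NFE	novel	novel	25.2	0.456	VUS	1.9
RPA1	HEM	1747283	SJALL041360	BALL	F	c.155_156del	p.L53Ifs*53	NFE	0.0008%	0.0020%	NA	NA	VUS	unavailable
RPA1	HEM	1747879	SJHL042034	HL	F	c.G171A	p.M57I	NFE	novel	novel	28	0.492	VUS	-0.2
RPA1	HEM	1747882	SJCBF147	AML	F	c.G174C	p.L58F	NFE	0.0009%	0.0010%	25.2	0.489	VUS	1.2
RPA1	HEM	1780546	SJTALL021675	TALL	A	c.C628T	p.R210C	Other	0.0038%	novel	35	0.594	VUS	0.6
RPA1	HEM	1782352	SJBALL020994	BALL	A	c.C756G	p.N252K	Other	0.0063%	0.0178%	26.6	0.267	VUS	0.2
RPA1	HEM	1782605	SJAML030416	AML	A	c.G856T	p.V286F	Other	0.0097%	0.0149%	33	0.373	VUS	0.6
RPA1	HEM	1782605	SJAML031075	AML	A	c.G856A	p.V286I	AMR	0.0410%	novel	16.3	0.373	VUS	0.6
RPA1	HEM	1782605	SJAML032052	AML	A	c.G856A	p.V286I	NFE	0.0410%	0.0286%	16.3	0.373	VUS	0.6
RPA1	HEM	1782605	SJAML032355	AML	A	c.G856A	p.V286I	NFE	0.0410%	0.0286%	16.3	0.373	VUS	0.6
RPA1	HEM	1782605	SJALL016427	BALL	A	c.G856T	p.V286F	NFE	0.0097%	0.0203%	33	0.373	VUS	0.6
RPA1	HEM	1782983	SJALL041859	BALL	B	c.G1082T	p.W361L	NFE	0.0008%	0.0019%	32	0.752	VUS	2.2
RPA1	HEM	1783867	SJHL041557	HL	B	c.G1123A	p.V375M	NFE	0.0021%	0.0049%	28.6	0.413	VUS	1.2
RPA1	HEM	1783909	SJTALL022093	TALL	B	c.C1165T	p.R389W	AMR	0.1763%	0.0028%	35	0.319	VUS	-0.9
RPA1	HEM	1783909	SJBALL001702	BALL	B	c.C1165T	p.R389W	NFE	0.1763%	0.0736%	35	0.319	VUS	-0.9
RPA1	HEM	1783909	SJALL015269	TALL	B	c.C1165T	p.R389W	NFE	0.1763%	0.0736%	35	0.319	VUS	-0.9
RPA1	HEM	1783909	SJBALL032592	BALL	B	c.C1165T	p.R389W	NFE	0.1763%	0.0736%	35	0.319	VUS	-0.9
RPA1	HEM	1787123	SJNHL042753	NHL	B	c.A1259T	p.Q420L	NFE	0.0019%	0.0042%	22	0.16	VUS	unavailable
RPA1	HEM	1787161	SJNHL042070	NHL	linker	c.G1297A	p.G433S	AFR	0.0157%	0.0508%	23.5	0.218	VUS	unavailable
RPA1	HEM	1787173	SJHL042469	HL	C	c.G1309A	p.G437R	AFR	0.0134%	0.1397%	24.4	0.286	VUS	unavailable
RPA1	HEM	1792053	SJALL018944	BALL	C	c.A1459G	p.N487D	NFE	novel	novel	28.6	0.564	VUS	0.2
RPA1	HEM	1792111	SJPHALL020033	BALL	C	c.A1517T	p.E506V	AMR	0.0034%	novel	32	0.387	VUS	-0.6
RPA1	HEM	1792111	SJALL015640	TALL	C	c.A1517T	p.E506V	AFR	0.0034%	0.0381%	32	0.387	VUS	-0.6
RPA1	HEM	1792132	SJERG020054	BALL	C	c.G1538A	p.R513H	NFE	0.0164%	0.0331%	35	0.535	VUS	0.4
RPA1	HEM	1792132	SJHL019322	HL	C	c.G1538A	p.R513H	NFE	0.0164%	0.0331%	35	0.535	VUS	0.4
RPA1	HEM	1795196	SJALL041325	BALL	C	c.G1621A	p.G541R	NFE	novel	novel	26.1	0.591	VUS	0.1
RPA1	HEM	1795196	SJNHL018781	NHL	C	c.G1621A	p.G541R	NFE	novel	novel	26.1	0.591	VUS	0.1
RPA1	HEM	1800399	SJALL018992	BALL	C	c.T1781G	p.V594G	NFE	0.0011%	0.0013%	26.5	0.569	VUS	3.3
RPA1	ST	1747265	SJNBL017162	NBL	F	c.A136G	p.M46V	NFE	0.0013%	0.0010%	22.2	0.28	VUS	0.1
RPA1	ST	1756468	SJRHB032408	Sarcoma_RMS	linker	c.G346A	p.V116M	AMR	novel	novel	23.4	0.151	VUS	0.6
RPA1	ST	1779063	SJWLM019906	WT	A	c.C563T	p.A188V	NFE	0.0161%	0.0078%	23.7	0.136	VUS	-0.4
RPA1	ST	1780603	SJNBL030203	NBL	A	c.G685A	p.E229K	AFR	0.0004%	novel	31	0.227	VUS	0
RPA1	ST	1782605	SJSTS019601	MEL	A	c.G856A	p.V286I	NFE	0.0403%	0.0254%	16.32	0.206	VUS	unavailable
RPA1	ST	1782605	SJMEL031366	Sarcoma_RMS	A	c.G856A	p.V286I	NFE	0.0403%	0.0254%	16.32	0.206	VUS	0.1
RPA1	ST	1782605	SJRHB000026	Sarcoma_synovial	A	c.G856A	p.V286I	NFE	0.0403%	0.0254%	16.32	0.206	VUS	-0.2
RPA1	ST	1782611	SJGCT019774	GCT	A	c.C862T	p.P288S	AFR	novel	novel	31	0.367	VUS	0.4
RPA1	ST	1783909	SJRB030058	RB	B	c.C1165T	p.R389W	NFE	0.1763%	0.0736%	35	0.319	VUS	-0.6
RPA1	ST	1783972	SJOS040162	Sarcoma_OS	B	c.A1228G	p.K410E	Other	novel	novel	23.3	0.148	VUS	0.1
RPA1	ST	1787123	SJST032198	PTC	B	c.A1259T	p.Q420L	NFE	0.0019%	0.0042%	22	0.16	VUS	0.8
RPA1	ST	1787140	SJEWS019204	Sarcoma_EWS	linker	c.T1276G	p.S426A	NFE	0.0021%	0.0049%	24.1	0.191	VUS	-0.9
RPA1	ST	1787161	SJNBL017202	NBL	linker	c.G1297A	p.G433S	AFR	0.0157%	0.0508%	23.5	0.218	VUS	0
RPA1	ST	1787173	SJSTS042513	Sarcoma_synovial	C	c.G1309A	p.G437R	AFR	0.0134%	0.1397%	24.4	0.286	VUS	unavailable
RPA1	ST	1787173	SJSTS019626	WT	C	c.G1309A	p.G437R	AFR	0.0134%	0.1397%	24.4	0.286	VUS	0.4
RPA1	ST	1792008	SJRB019561	RB	C	c.C1414T	p.R472C	AFR	0.0026%	0.0212%	35	0.542	VUS	-0.2
RPA1	ST	1792111	SJNPC019502	NPC	C	c.A1517T	p.E506V	AFR	0.0034%	0.0381%	32	0.387	VUS	0.6
RPA1	ST	1792120	SJRB017939	RB	C	c.A1526G	p.N509S	NFE	0.0008%	novel	20.6	0.141	VUS	0.2
RPA1	ST	1795196	SJNBL018730	NBL	C	c.G1621A	p.G541R	NFE	novel	novel	26.1	0.591	VUS	0.6
RPA1	ST	1795226	SJNBL017207	NBL	C	c.A1651C	p.K551Q	NFE	novel	novel	22.7	0.282	VUS	unavailable
RPA1	ST	1800386	SJOS018814	Sarcoma_OS	C	c.A1768G	p.T590A	AMR	0.0050%	0.0325%	23.1	0.15	VUS	-0.2
RPA1	ST	1800407	SJNBL042729	NBL	C	c.G1789A	p.V597M	NFE	0.0011%	0.0014%	27.8	0.292	VUS	unavailable
RPA1	CNS	1778987	SJLGG031132	LGG	linker	c.A487G	p.K163E	NFE	0.0008%	0.0010%	16.67	0.128	VUS	unavailable
RPA1	CNS	1782296	SJEPD030782	EPD	A	c.C700G	p.R234G	NFE	0.0008%	0.0019%	28	0.598	VUS	1.5
RPA1	CNS	1782605	SJMB030776	MB	A	c.G856T	p.V286F	AMR	0.0097%	novel	33	0.373	VUS	-0.4
RPA1	CNS	1782646	SJMB032506	MB	linker	c.G897C	p.Q299H	NFE	novel	novel	22.4	0.081	VUS	-0.2
RPA1	CNS	1787173	SJHGG117	HGG	C	c.G1309A	p.G437R	AFR	0.0134%	0.1397%	24.4	0.286	VUS	unavailable
RPA1	CNS	1787173	SJHGG030703	HGG	C	c.G1309A	p.G437R	AFR	0.0134%	0.1397%	24.4	0.286	VUS	unavailable
RPA1	CNS	1792075	SJHGG067	HGG	C	c.A1481G	p.Q494R	EAS	novel	novel	23.5	0.202	VUS	-0.1
RPA1	CNS	1792089	SJLGG030365	LGG	C	c.C1495T	p.R499C	AMR	0.0052%	0.0171%	35	0.435	VUS	-0.1
RPA1	CNS	1792113	SJCNS018575	MB	C	c.T1519C	p.F507L	NFE	novel	novel	28.7	0.179	VUS	0.6
RPA1	CNS	1792132	SJLGG046	LGG	C	c.G1538A	p.R513H	NFE	0.0164%	0.0331%	35	0.535	VUS	0.4
RPA1	CNS	1792139	SJHGG100	HGG	C	c.C1545G	p.I515M	NFE	0.0008%	novel	17.81	0.074	VUS	0.5
RPA1	CNS	1800398	SJST032495	MB	C	c.G1780A	p.V594M	NFE	novel	novel	33	0.419	VUS	0.7
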