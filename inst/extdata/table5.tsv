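rsid	gene	maf	function	gnomad_aggregated_pct
rs2984348	HDAC8	0.5	Enhancer	28.56
rs10849885	KDM2B	0.5	Synonymous/EMAR	37.96
rs3814177	TET1	0.5	3'UTR	<0.01
rs86312	NAGLU	0.48	Missense/EMAR	46.9
rs732770	ACACA	0.47	Enhancer	NA
rs6087988	DNMT3B	0.47	TF binding/Enhancer	<0.01
rs5969751	RBBP7	0.47	3'UTR	NA
rs1667619	TET3	0.47	Synonymous/EMAR+Enhancer	NA
rs2597512	HDAC11	0.45	Intronic/Enhancer	<0.01
rs112114764	HDAC5	0.41	Promoter	48.94
rs828867	TET3	0.41	3'UTR	NA
rs9929218	CDH1	0.4	Intronic/Enhancer	27.94
rs2107595	HDAC9	0.4	Enhancer/EMAR	19.8
rs2047409	TET2	0.39	Missense/EMAR	48.91
rs11913442	EP300	0.38	Promoter	55.61
rs7098181	JMJD1C	0.37	Intronic/EMAR	37.99
rs35291459	HDAC4	0.36	Synonymous	4.22
rs2301718	TET2	0.33	Intronic/Promoter/EMAR	23.48
rs7776786	HDAC9	0.32	Intronic/Enhancer	38.51
rs13389265	HDAC4	0.29	Intronic/Enhancer	16.54
rs2092563	EP300	0.25	Intronic/Enhancer	23.55
rs10426930	KDM4B	0.25	Intronic/EMAR/Enhancer	30.11
rs56185013	TET2	0.25	3'UTR	17.15
rs2288940	DNMT1	0.23	Intronic/CTCF/Enhancer	<0.01
rs2731338	HDAC11	0.22	Enhancer	72.62
rs80052686	EZH2	0.21	Intronic/Promoter	16.4
rs2926337	MBD2	0.19	Intronic/EMAR/Enhancer	25.57
rs12223627	MTA2	0.15	Intronic/EMAR/Enhancer	21.47
rs76714272	ACACB	0.14	Intronic/Enhancer	17.77
rs73015138	DNMT1	0.12	Intronic/Enhancer	13.31
rs11657063	KDM6B	0.1	EMAR	10.13
rs58644382	HDAC4	0.09	Enhancer	8.34
rs73107993	HDAC7	0.09	Intronic/CTCF	NA
rs12226402	SIRT3	0.09	3'UTR/EMAR/Enhancer	5.29
rs11168254	HDAC7	0.05	Promoter	4.37
rs41274064	JMJD1C	0.05	Missense/inframeshift	2.48
rs4986782	NAT1	0.05	Missense	1.47
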