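rsid	gene	maf	function	gnomad_aggregated_pct
rs1931537	AR	0.5	3'UTR	87.11
rs2116942	DNMT1	0.5	Missense	54.22
rs1935	JMJD1C	0.5	Missense	NA
rs7962128	KDM2B	0.5	3'UTR	67.31
rs7042372	KDM4C	0.5	Intronic/EMAR/Enhancer	36.14
rs5969750	RBBP7	0.5	3'UTR	NA
rs7670522	TET2	0.5	3'UTR	NA
rs739842	HDAC7	0.49	Intronic/Enhancer	69.7
rs661818	HDAC9	0.44	Intronic/Enhancer	NA
rs2454206	TET2	0.42	Missense	29.48
rs12241767	TET1	0.4	Missense	NA
rs609292	HDAC5	0.38	Intronic/Enhancer	59.02
rs7070693	JMJD1C	0.37	Intronic/EMAR/Enhancer	NA
rs4807687	KDM4B	0.37	Intronic/EMAR/Enhancer	27.83
rs9925964	KAT8	0.36	Splicing/Enhancer/EMAR	32.65
rs7812296	HDAC9	0.35	3'UTR	56.96
rs9795476	SIRT3	0.35	Intronic/EMAR	NA
rs34550543	KDM4A	0.31	Intronic/EMAR/Enhancer	NA
rs62621450	TET2	0.3	Missense	4.33
rs1997797	DNMT3B	0.29	Splicing	<0.01
rs601999	NAGLU	0.29	Synonymous/EMAR/Enhancer	NA
rs79491673	MBD2	0.27	EMAR/Enhancer	26.94
rs57917116	KDM2B	0.26	Intronic/EMAR/Enhancer	22.21
rs7208787	KDM6B	0.24	EMAR	15.87
rs7661349	TET2	0.24	Intronic/Promoter/EMAR	NA
rs4507125	HDAC4	0.22	Enhancer	NA
rs13632	HDAC7	0.18	3'UTR	78.95
rs591939	NAGLU	0.18	Synonymous/EMAR/Enhancer	17.07
rs58324296	KDM4B	0.16	3'UTR/EMAR	NA
rs2288937	DNMT1	0.12	Intronic/Enhancer	<0.01
rs71524263	HDAC9	0.08	Intronic/OpenChromatin/EMAR	11.44
rs41274072	JMJD1C	0.05	Missense	3.16
rs61031471	KDM6B	0.05	Missense	<0.01
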