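rsid	gene	function	cpg_situation
rs1038376	CYP2B6	3'UTR	Forming
rs138264188	CYP2B6	Missense	Disruptive
rs141666881	CYP2B6	Missense	Disruptive
rs142421637	CYP2B6	Missense	Disruptive
rs148009906	CYP2B6	Missense	Disruptive
rs1969136524	CYP2B6	Missense	Forming
rs200458614	CYP2B6	Missense	Disruptive
rs3181842	CYP2B6	3UTR	Disruptive
rs3211371	CYP2B6	Missense	Disruptive
rs36118214	CYP2B6	Intronic	Disruptive
rs373442191	CYP2B6	Missense	Disruptive
rs374099483	CYP2B6	Missense	Disruptive
rs3786547	CYP2B6	Intronic	Forming
rs535039125	CYP2B6	Missense	Disruptive
rs553968231	CYP2B6	Missense	Disruptive
rs58871670	CYP2B6	Missense	Disruptive
rs707265	CYP2B6	Missense	Forming
rs7246465	CYP2B6	3'UTR	Forming
rs750671397	CYP2B6	Missense	Forming
rs752695347	CYP2B6	Missense	Disruptive
rs764288403	CYP2B6	Missense	Disruptive
rs772413158	CYP2B6	Missense	Disruptive
rs8192709	CYP2B6	Missense	Disruptive
rs4244285	CYP2C19	Synonymous	Disruptive
rs3814637	CYP2C19	Intronic	Disruptive
rs183701923	CYP2C19	Missense	Disruptive
rs140278421	CYP2C19	Missense	Disruptive
rs145119820	CYP2C19	Missense	Disruptive
rs17878459	CYP2C19	Missense	Forming
rs3758581	CYP2C19	Missense	Forming
rs181297724	CYP2C19	Missense	Forming
rs118203756	CYP2C19	Missense	Forming
rs138142612	CYP2C19	Missense	Disruptive
rs72552267	CYP2C19	Missense	Disruptive
rs749678783	CYP2C19	Missense	Forming
rs764137538	CYP2C19	Missense	Disruptive
rs200346442	CYP2C19	Missense	Disruptive
rs200150287	CYP2C19	Missense	Disruptive
rs763625282	CYP2C19	Missense	Forming
rs150152656	CYP2C19	Missense	Disruptive
rs7902257	CYP2C19	Intronic	Disruptive
rs370803989	CYP2C19	Missense	Disruptive
rs145328984	CYP2C19	Missense	Disruptive
rs41291556	CYP2C19	Missense	Forming
rs1058172	CYP2D6	Missense	Disruptive
rs1065852	CYP2D6	Missense	Forming
rs1080985	CYP2D6	Missense	Forming + Disruptive
rs1080989	CYP2D6	Intronic	Disruptive
rs111564371	CYP2D6	Intronic	Forming
rs112568578	CYP2D6	Missense	Disruptive
rs1230912765	CYP2D6	Missense	Disruptive
rs138417770	CYP2D6	Missense	Forming + Disruptive
rs16947	CYP2D6	Missense	Disruptive
rs1985842	CYP2D6	Intronic	Forming
rs28371699	CYP2D6	Intronic	Disruptive
rs28371726	CYP2D6	Missense	Forming
rs28371738	CYP2D6	Intronic	Forming
rs35742686	CYP2D6	Frameshift	Forming
rs3892097	CYP2D6	Splice Acceptor	Forming
rs745746329	CYP2D6	Missense + Inframeshift	Disruptive
rs76187628	CYP2D6	Missense	Forming
rs777560972	CYP2D6	Missense	Disruptive
rs165599	COMT	3'UTR	Disruptive
rs174699	COMT	Intronic	Disruptive
rs2239393	COMT	Intronic	Forming
rs4633	COMT	Synonymous	Disruptive
rs4646316	COMT	Intronic	Disruptive
rs4680	COMT	Missense	Disruptive
rs5746849	COMT	Intronic + Enhancer	Forming
rs6269	COMT	3utr + CTCF	Forming
rs7287550	COMT	Intronic	Forming
rs740603	COMT	Intronic + Enhancer	Forming
rs933271	COMT	Intronic + Enhancer	Forming
rs1203844	CYP3A4	Intronic	Disruptive
rs12721627	CYP3A4	Missense	Forming
rs35599367	CYP3A4	Missense	Disruptive
rs3735451	CYP3A4	Intronic	Forming
rs4646437	CYP3A4	Missense	Disruptive
rs4986907	CYP3A4	Missense	Disruptive
rs4986909	CYP3A4	Missense	Forming
rs4986910	CYP3A4	Missense	Forming
rs12596638	FTO	Intronic	Disruptive
rs16952570	FTO	Intronic	Forming
rs79206939	FTO	Missense	Disruptive
rs9940629	FTO	Intronic	Forming
rs1801133	MTHFR	Missense	Disruptive
rs2274976	MTHFR	Missense	Disruptive
rs3737967	MTHFR	Missense	Disruptive
rs12720461	CYP1A2	Intronic	Disruptive
rs762551	CYP1A2	Intronic	Forming
rs2058878	GRIN2B	Intronic	Forming
rs1806201	GRIN2B	Synonymous	Disruptive
rs1799930	NAT2	Missense	Disruptive
rs1042522	TP53	Missense	Forming
rs1734787	MECP2	Intronic	Forming
rs759922342	CDKN2A	Missense	Forming
rs2304429	DNMT3A	Intronic	Disruptive
rs9829896	KAT2B	Intronic	Disruptive
rs7166737	SIN3A	Intronic	Forming
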