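gene	epigenetic_process	relevance_score	n_significant_pgx	n_cpg_pgx_snp
CYP2B6	Demethylation	10.40399	383	23
CYP2C19	Demethylation	7.372463	949	21
CYP2D6	Demethylation	10.74248	733	18
COMT	Methylation	18.34278	121	11
CYP3A4	Demethylation	12.93115	282	8
FTO	Demethylation	14.13657	11	4
MTHFR	Methylation	17.11379	151	3
CYP1A2	Demethylation	10.08261	84	2
GRIN2B	Methylation	22.91825	5	2
NAT2	Acetylation	40.88459	155	1
TP53	Methylation	20.33753	11	1
MECP2	Methylation	38.57069	3	1
CDKN2A	Methylation	26.32699	1	1
DNMT3A	Methylation	25.22683	1	1
KAT2B	Acetylation	25.24294	1	1
SIN3A	Deacetylation	5.800954	1	1
ACSS2	Acetylation	19.99729	2	0
HDAC1	Acetylation	17.49331	2	0
MGMT	Methylation	35.78139	1	0
EHMT2	Methylation	21.40185	1	0
RASSF1	Methylation	18.96314	1	0
SIRT1	Acetylation	17.80751	1	0
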