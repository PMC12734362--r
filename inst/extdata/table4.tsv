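gene	epigenetic_process	relevance_score	n_refined_snps	n_cpg_snps
TET2	Demethylation	11.1206	148	42
JMJD1C	Demethylation	10.36812	174	35
HDAC9	Deacetylation	9.43903	130	26
KDM4B	Demethylation	8.900465	50	22
KDM2B	Demethylation	8.859386	35	14
GRIN2A	Methylation	21.42977142	59	13
HDAC7	Deacetylation	7.25612	34	13
ACAA2	Acetylation	15.70166	52	12
HDAC4	Deacetylation	8.759825	34	12
TET1	Demethylation	12.24121	34	12
CDH1	Methylation	18.68703842	27	10
KDM4C	Demethylation	9.926583	40	10
DNMT3B	Methylation	25.82717514	29	9
HDAC11	Deacetylation	5.730898	10	8
SLC33A1	Acetylation	21.82475	20	7
ACACA	Acetylation	36.13462	17	6
DNMT1	Methylation	33.36149979	25	6
KAT8	Acetylation	15.52563	11	6
NAGLU	Acetylation	20.19837	6	5
SIRT3	Deacetylation	9.975184	23	5
EP300	Acetylation/Deacetylation	34.95532/8.402884	23	4
HDAC5	Deacetylation	7.853906	16	4
MBD2	Methylation	28.06098938	20	4
PRMT5	Methylation	19.25225449	1	1
ACACB	Acetylation	22.3765	12	3
ACSS1	Acetylation	15.36008	14	3
AR	Methylation	19.19925117	8	3
HDAC2	Acetylation/Deacetylation	14.69187/10.94646	10	3
KDM4A	Demethylation	11.33719	20	3
KDM6B	Demethylation	9.335324	11	3
ALKBH5	Demethylation	10.9696	10	2
CREBBP	Acetylation/Deacetylattion	23.61674/4.776761	7	2
EZH2	Methylation	17.65591049	6	2
KDM1A	Demethylation	15.8258	9	2
NAT1	Acetylation	15.67783	5	2
RBBP7	Deacetylation	4.671091	4	2
TET3	Demethylation	10.49595	19	2
ALKBH1	Demethylation	8.964048	4	1
HDAC8	Deacetylation	8.406831	3	1
KAT2A	Acetylation	18.43493	7	1
KAT5	Acetylation	21.23479	5	1
KDM3A	Demethylation	10.28292	2	1
KDM6A	Demethylation	8.683799	2	1
MLH1	Methylation	22.98958206	1	1
MTA2	Deacetylation	4.632188	3	1
PRMT1	Methylation	21.30334854	3	1
SIRT6	Deacetylation	10.88304	1	1
TDG	Demethylation	8.484888	1	1
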