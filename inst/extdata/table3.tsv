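gene	relevance_score	n_significant_pgx	n_cpg_pgx_snp	n_variant_types	n_formations	n_disruptions	n_pubmed_titles
CYP2D6	10.74248	733	18	5	10	10	2658
CYP2C19	7.372463	949	21	3	7	14	2057
CYP2B6	10.40399	383	23	3	6	17	580
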