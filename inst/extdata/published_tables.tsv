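# gaphdna published per-strain counts and printed values (source tables 1-3)
# repair_efficiency: printed mean WT-normalized His+:Leu+ ratio
# co_count/nco_count: plasmid-stability partition of His+ transformants
# n_sequenced: NCO products sequenced (NA where not printed)
# uni/bi/cleavage_count: hDNA-detected NCO events by class
# printed_*: the published derived cells, for reproduction checks
strain	source_table	repair_efficiency	n_transformations	co_count	nco_count	n_sequenced	uni_count	bi_count	cleavage_count	printed_co_eff	printed_nco_eff	printed_uni_prop_pct	printed_uni_eff	printed_bi_prop_pct	printed_bi_eff
WT	1	1.00	36	41	412	249	141	18	0	0.09	0.91	89	0.81	11	0.10
mph1	1	1.04	24	89	373	242	150	26	0	0.20	0.84	85	0.71	15	0.12
sgs1	1	0.72	12	26	150	285	136	13	0	0.11	0.62	91	0.56	9	0.05
srs2	1	0.31	40	86	257	254	102	27	0	0.08	0.23	79	0.19	21	0.05
mph1_sgs1	2	0.87	12	41	145	NA	36	10	1	0.19	0.67	77	0.52	21	0.14
mph1_srs2	3	0.55	11	52	127	85	38	5	0	0.16	0.39	88	0.34	12	0.05
srs2-860	3	0.80	12	26	152	NA	29	4	0	0.12	0.68	88	0.60	12	0.08
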