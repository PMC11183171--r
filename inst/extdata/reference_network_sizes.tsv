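network	nodes	edges	avg_degree	density	cross_edges	cross_pct
bacteria	415	1669	8.04	0.019	NA	NA
rhizobia	121	103	1.70	0.014	NA	NA
bacteria_am_fungi	597	3221	10.8	0.018	778	24.2
rhizobia_am_fungi	303	813	5.37	0.018	233	28.7
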