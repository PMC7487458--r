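chrom	start	end	band	dup_ipsc	del_ipsc	dup_ctrl	del_ctrl	n_ipsc	n_ctrl	stratum
chr4	62690392	62945462	q13.1	5	0	1	0	82	1093	all
chr4	92930866	94220988	q22.1-q22.2	38	2	0	1	82	1093	all
chr5	147202104	147449067	q32	8	0	0	0	82	1093	all
chr6	94291842	94849832	q16.1	2	2	0	0	82	1093	all
chr7	121549706	122245008	q31.32	12	0	1	0	82	1093	all
chr10	54932474	55398702	q21.1	6	0	0	0	82	1093	all
chr13	55695571	56471149	q21.1	5	0	0	2	82	1093	all
chr20	29620219	31558271	q11.21	5	0	0	0	82	1093	all
chrX	112880475	113795367	q23	27	0	0	0	42	568	female_only
chrX	114766295	114897324	q23	8	0	0	0	42	568	female_only
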