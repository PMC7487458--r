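# ipscnv 0.1.0; coordinates: 1-based inclusive
sample_id	chrom	start	end	direction	n_probes	length
EX01_S1	chr1	80001	300001	gain	12	220001
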