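sample_id	donor_id	role	sex
EX01_P	EX01	parental	female
EX01_S1	EX01	ipsc	female
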