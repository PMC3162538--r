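dataset	n_perfect	n_compound	total_mbp	gc_percent
BES	234	6	1.74	38.3
EST	821	26	3.82	42.3
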