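locus	n_alleles	size_min	size_max	he
gssr3	20	285	335	0.86
gssr4	29	253	320	0.91
gssr6	19	283	331	0.89
gssr9	22	281	337	0.77
gssr16	16	229	346	0.82
gssr35	21	144	219	0.87
gssr65	10	404	433	0.79
gssr85	14	219	294	0.84
gssr111	21	284	390	0.79
gssr134	18	272	334	0.8
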