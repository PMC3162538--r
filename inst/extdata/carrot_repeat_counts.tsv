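dataset	unit_len	count
BES	2	39
BES	3	97
BES	4	57
BES	5	27
BES	6	7
BES	7	4
BES	8	3
EST	2	207
EST	3	411
EST	4	129
EST	5	29
EST	6	39
EST	7	4
EST	8	2
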