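gene_id	residue_number	recurrence_count
NF1	1276	7
NF1	844	6
NF1	489	5
NF1	176	2
BRAF	600	500
KRAS	12	800
KRAS	13	200
H3F3A	27	300
PIK3CA	545	250
EGFR	598	12
TP53	273	60
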