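gene_a	gene_b
KIAA1549	BRAF
ETV6	NTRK3
MYB	QKI
FGFR1	TACC1
FGFR3	TACC3
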