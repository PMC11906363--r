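gene_id	role	in_tier1_list	fusion_only	activating_intragenic_del
ACVR1	oncogene	TRUE	FALSE	FALSE
ASXL1	tsg	TRUE	FALSE	FALSE
ATM	tsg	TRUE	FALSE	FALSE
ATRX	tsg	TRUE	FALSE	FALSE
BCOR	tsg	TRUE	FALSE	FALSE
BRAF	oncogene	TRUE	FALSE	FALSE
CCND2	oncogene	TRUE	FALSE	FALSE
CDK4	oncogene	TRUE	FALSE	FALSE
CDK6	oncogene	TRUE	FALSE	FALSE
CDKN2A	tsg	TRUE	FALSE	FALSE
CDKN2B	tsg	TRUE	FALSE	FALSE
EGFR	oncogene	TRUE	FALSE	TRUE
FGFR1	oncogene	TRUE	FALSE	FALSE
H3F3A	oncogene	TRUE	FALSE	FALSE
HIST1H3B	oncogene	TRUE	FALSE	FALSE
HIST1H3C	oncogene	TRUE	FALSE	FALSE
HIST2H3C	oncogene	TRUE	FALSE	FALSE
ID2	oncogene	TRUE	FALSE	FALSE
KDM6B	tsg	TRUE	FALSE	FALSE
KDR	oncogene	TRUE	FALSE	FALSE
KIT	oncogene	TRUE	FALSE	FALSE
KRAS	oncogene	TRUE	FALSE	FALSE
MET	oncogene	TRUE	FALSE	FALSE
MYC	oncogene	TRUE	FALSE	FALSE
MYCN	oncogene	TRUE	FALSE	FALSE
NF1	tsg	TRUE	FALSE	FALSE
NTRK1	oncogene	TRUE	TRUE	FALSE
NTRK2	oncogene	TRUE	TRUE	FALSE
NTRK3	oncogene	TRUE	TRUE	FALSE
PDGFRA	oncogene	TRUE	FALSE	TRUE
PIK3CA	oncogene	TRUE	FALSE	FALSE
PIK3R1	tsg	TRUE	FALSE	FALSE
PPM1D	oncogene	TRUE	FALSE	FALSE
PTEN	tsg	TRUE	FALSE	FALSE
RB1	tsg	TRUE	FALSE	FALSE
SETD2	tsg	TRUE	FALSE	FALSE
TERT	oncogene	TRUE	FALSE	FALSE
TOP3A	tsg	TRUE	FALSE	FALSE
TP53	tsg	TRUE	FALSE	FALSE
CREBBP	tsg	FALSE	FALSE	FALSE
MSH6	tsg	FALSE	FALSE	FALSE
SMARCB1	tsg	FALSE	FALSE	FALSE
IDH1	oncogene	FALSE	FALSE	FALSE
ALK	oncogene	FALSE	TRUE	FALSE
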