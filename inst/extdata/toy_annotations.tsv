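chrom	pos	ref	alt	gene	transcript	consequence	maf_1000g_eur	maf_exac	maf_inhouse	cadd_phred	svm_label	clinvar_flag
1	100	A	G	GENEA	TX_GENEA	missense	0	0	0	25	damaging	FALSE
1	200	A	G	GENEA	TX_GENEA	frameshift	0	0	0	.	.	FALSE
1	300	A	G	GENEA	TX_GENEA	missense	0	0	0	25	tolerated	FALSE
1	400	A	G	GENEA	TX_GENEA	missense	0	0	0	25	damaging	FALSE
2	100	A	G	GENEB	TX_GENEB	missense	0	0.08	0	25	damaging	FALSE
2	200	A	G	GENEB	TX_GENEB	synonymous	0	0	0	.	.	FALSE
2	300	A	G	GENEB	TX_GENEB	missense	0	0	0	25	tolerated	TRUE
2	400	A	G	GENEB	TX_GENEB	missense	0	0	0	10	damaging	FALSE
X	100	A	G	GENEC	TX_GENEC	missense	0	0	0	15	tolerated	FALSE
X	200	A	G	GENEC	TX_GENEC	frameshift	0	0	0	.	.	FALSE
X	300	A	G	GENEC	TX_GENEC	stop_gained	0	0	0	.	.	TRUE
X	400	A	G	GENEC	TX_GENEC	inframe_indel	0	0	0	.	.	FALSE
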