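##fileformat=VCFv4.2
##INFO=<ID=RD,Number=1,Type=Integer,Description="Read depth">
##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">
##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4	S5	S6
1	100	.	A	G	.	PASS	RD=8;MQ=60;QD=15	GT	0/1	0/0	0/0	0/0	0/0	0/0
1	200	.	A	G	.	PASS	RD=50;MQ=30;QD=15	GT	0/0	0/1	0/0	0/0	0/0	0/0
1	300	.	A	G	.	PASS	RD=50;MQ=60;QD=1.5	GT	0/0	0/0	0/1	0/0	0/0	0/0
1	400	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/1	0/1	0/1	0/0	0/0	0/0
2	100	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/1	0/1	0/0	0/0	0/0	0/0
2	200	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/0	0/0	0/1	0/0	0/0
2	300	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/1	0/0	0/0	0/0	0/0	0/0
2	400	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/1	0/1	0/0	0/0	0/0
X	100	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/0	0/0	0/1	0/0	0/0
X	200	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/0	0/0	0/0	0/1	0/0
X	300	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/0	0/0	0/0	0/0	1
X	400	.	A	G	.	PASS	RD=50;MQ=60;QD=15	GT	0/0	0/0	0/0	0/0	0/1	0/0
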