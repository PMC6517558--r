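module	age_min	age_max	raw_min	raw_max	score
2	5	7	0	6	2
2	5	7	7	12	5
2	5	7	13	18	8
2	5	7	19	26	10
3	5	7	0	4	1
3	5	7	5	8	3
3	5	7	9	13	5
3	5	7	14	19	7
3	5	7	20	22	9
3	5	7	23	28	10
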