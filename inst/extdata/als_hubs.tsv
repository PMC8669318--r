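rank	node	degree
1	TP53	236
2	SOD1	211
3	CDC5L	186
4	SNW1	173
5	VCP	172
6	AR	171
7	DLD	155
8	DISC1	148
9	NEK4	138
10	HSP90AA1	128
11	EGFR	125
12	DLST	124
13	PDHA1	122
14	ATXN1	119
15	HTT	117
16	SQSTM1	117
17	APP	114
18	PSEN1	110
19	EP300	108
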