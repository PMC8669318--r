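rank	node	betweenness
1	VCP	0.06587026
2	TP53	0.06480069
3	SOD1	0.0560067
4	AR	0.05264571
5	DISC1	0.05158762
6	ATXN1	0.04441985
7	SQSTM1	0.03839771
8	APP	0.03540357
9	CDC5L	0.03374739
10	PSEN1	0.03306112
11	EGFR	0.03113805
12	SNW1	0.02913541
13	HSP90AA1	0.02680708
14	HTT	0.02414826
15	DLD	0.02369741
16	PDHA1	0.02203444
17	NEK4	0.02047508
18	PARK7	0.02043984
19	MAPT	0.01992754
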