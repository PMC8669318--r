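node	M1	M2	M3	M4	M5
CDC5L	3	14	2	28	13
SNW1	3	13	1	26	14
TP53	4	9	0	22	14
NEK4	0	11	0	16	9
HSP90AA1	1	3	0	10	15
SOD1	5	4	0	5	14
EGFR	1	5	0	6	13
DLD	4	5	0	8	8
VCP	5	5	0	8	5
AR	0	4	0	6	12
PDHA1	0	3	2	5	6
ATXN1	1	4	0	2	7
PSEN1	3	4	1	5	5
DISC1	0	1	0	6	4
APP	0	3	0	5	12
SQSTM1	1	3	0	11	15
HTT	4	5	0	10	13
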