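module	nodes	edges
1	11	44
2	41	103
3	15	34
4	76	176
5	65	140
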