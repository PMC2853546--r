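region	n	pd	pd_min	pd_max	pd_norm	hc	hc_min	hc_max	hc_norm
R6	21	47	25	87	0.35	14	3	25	0.50
R3	11	28	10	67	0.32	16	1	27	0.58
R2	18	33	20	81	0.21	7	3	25	0.18
R4	7	14	6	55	0.16	5	1	27	0.15
R5	18	29	20	81	0.15	5	3	25	0.09
R1	5	10	4	48	0.14	7	1	28	0.22
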