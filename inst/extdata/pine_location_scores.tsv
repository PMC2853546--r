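location	n	ad	ad_min	ad_max	ad_norm	hc	hc_min	hc_max	hc_norm
Landes	6	2.45	0.33	7.14	0.31	6	1	10	0.56
Pantelleria	9	1.67	0.37	5.66	0.25	3	1	10	0.22
Leiria	8	0.73	0.36	6.06	0.06	1	1	10	0.00
Sardinia	9	0.70	0.37	5.66	0.06	2	1	10	0.11
Morocco	8	0.69	0.36	6.06	0.06	1	1	10	0.00
Corsica	8	0.68	0.36	6.06	0.06	1	1	10	0.00
Liguria	5	0.64	0.31	8.06	0.04	2	1	11	0.10
Moncao	6	0.33	0.33	7.14	0.00	1	1	10	0.00
Tuscany	5	0.31	0.31	8.06	0.00	1	1	11	0.00
Alcacier	5	0.31	0.31	8.06	0.00	1	1	11	0.00
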