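vertex	haplotype
v1	a1
v2	a2
v4	a3
v5	a4
v6	a5
v8	a6
v9	a7
v10	a8
v12	a9
v13	a10
v14	a11
v16	a12
v17	a13
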