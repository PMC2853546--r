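vertex1	vertex2	length
v1	v2	1
v2	v3	1
v3	v4	1
v4	v5	1
v5	v6	1
v6	v7	1
v7	v8	1
v8	v9	1
v9	v10	1
v10	v11	1
v11	v12	1
v12	v13	1
v13	v14	1
v14	v15	1
v15	v16	1
v16	v17	1
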