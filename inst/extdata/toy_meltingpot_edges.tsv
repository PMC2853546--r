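vertex1	vertex2	length
u1	m1	1
u1	m2	1
u1	m3	1
u1	m4	1
u1	m5	1
u1	m6	1
u1	m7	1
u2	m8	1
u2	m9	1
u2	m10	1
u2	m11	1
u2	m12	1
u2	m13	1
u1	w1	1
w1	w2	1
w2	u2	1
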