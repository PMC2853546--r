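vertex	haplotype
m1	b1
m2	b2
m3	b3
m4	b4
m5	b5
m6	b6
m7	b7
m8	b8
m9	b9
m10	b10
m11	b11
m12	b12
m13	b13
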