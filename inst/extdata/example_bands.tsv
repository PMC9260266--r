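locus_id	s1.H	s1.M	s2.H	s2.M
L1	1	1	1	1
L2	1	0	0	1
L3	0	1	0	0
L4	0	0	1	1
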