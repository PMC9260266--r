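sample_id	tissue	stage	dose_uM	replicate
s1	root	M	0	1
s2	root	M	50	1
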