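s	eps	mu	r
0.05	1	1e-05	0.01
0.05	1	1e-05	0.05
0.05	1	1e-05	0.1
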