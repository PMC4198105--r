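channel	pct_minus2	pct_minus1	pct_plus1	pct_plus2
114	0	1	5.9	0.2
115	0	2	5.6	0.1
116	0	3	4.5	0.1
117	0.1	4	3.5	0.1
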