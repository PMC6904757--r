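label	observed	EX_glc	EX_ac
DSM319	0.106	1.52	0.15
MS941	0.11	1.62	0.17
WH320	0.426	5.17	0.6
WH323a	0.096	1.31	0.17
WH323b	0.107	1.53	0.16
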