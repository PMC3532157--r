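gene	sense_pct	antisense_pct
NC12	10.12	1.17
NC25_gigA	1.45	0.13
subtilisin_like_protease	2.60	0.03
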