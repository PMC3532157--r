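rank	match_id	identification	strand	mean_pct
1	SRR493691.19548	NC12 (epichloae specific)	sense	10.12
2	SRR493691.12929	Secreted antifungal protein (small, cysteine-rich)	sense	6.34
3	SRR493690.59639	Secreted, unknown function (small, cysteine-rich)	sense	4.60
4	SRR493691.55163	Secreted subtilisin-like protease	sense	2.60
5	SRR493691.16186	Unknown function (epichloae specific)	sense	2.58
6	SRR493691.34496	Secreted, unknown function (epichloae specific)	sense	1.90
7	SRR493691.15406	Secreted NC25 (gigA) (epichloae specific)	sense	1.45
8	SRR493691.46417	Secreted, conidiation associated	sense	1.37
9	SRR493691.19548	NC12 (epichloae specific)	antisense	1.17
10	SRR493691.31334	Unknown function (epichloae specific)	sense	1.14
11	SRR493691.38494	Unknown function, glucose repressible Grg1	sense	1.04
12	SRR493690.32961	Secreted, unknown function	sense	1.02
13	SRR493691.32405	Secreted, unknown function (small, cysteine-rich)	sense	1.01
14	SRR493691.6870	Secreted, unknown function (small, cysteine-rich)	sense	0.97
15	AFRX01000547	Secreted, unknown function (small, cysteine-rich)	sense	0.87
16	SRR493691.52692	Unknown function (epichloae specific)	sense	0.84
17	SRR493691.35651	Secreted, unknown function (epichloae specific)	sense	0.76
18	SRR493691.71157	Mismatched base pair and cruciform DNA recognition protein	sense	0.62
19	SRR493691.48167	Secreted, unknown function (epichloae specific)	sense	0.62
20	SRR493691.69494	Secreted, unknown function, RNase domain	sense	0.61
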