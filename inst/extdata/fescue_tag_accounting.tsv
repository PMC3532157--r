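sample	replicate	total	with_anchor	after_polyA	plant_mapped	fungal_mapped
Eminus	1	10266193	7208225	7194891	4346031	NA
Eminus	2	8048623	5629653	5613295	3303965	NA
Eminus	3	6015959	4019984	4012492	2269416	NA
Eplus	1	5415607	3044831	3041847	1137472	43199
Eplus	2	6165530	4031091	4025153	2160008	112294
Eplus	3	5736324	3364721	3361001	1471380	71927
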