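category	up_n	down_n
Autophagy	4	0
Carbohydrate metabolic process	0	2
Cell redox homeostasis	0	4
Cellular carbohydrate metabolic process	0	1
Cellular component organization	3	3
Cellular nitrogen compound metabolic process	2	2
DNA modification	2	0
DNA replication	0	1
Generation of precursor metabolites and energy	1	5
Lipid metabolic process	0	7
Meiosis	1	0
Metabolic process	3	2
Organ senescence	2	0
Oxidation reduction process	1	1
Photosynthesis	9	1
Protein metabolic process	2	0
Protein modification process	4	6
Protein targeting	3	3
Protein ubiquitination	1	1
Regulation of hydrolase activity	2	0
Response to abiotic stimulus	1	1
Response to biotic stimulus	1	1
Response to endogenous stimulus	0	1
Response to metal ion	1	1
Response to stress	8	10
RNA metabolic process	0	6
Signal transduction	2	8
Transcription, DNA-dependent	1	5
Translation	0	9
Transport	6	19
Biological process	3	19
No blastx match found	7	9
No match in NCBI database	2	9
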