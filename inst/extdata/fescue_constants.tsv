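key	value
plant_contigs	19496
plant_singletons	49321
fungal_contigs	13381
fungal_singletons	22616
unique_fungal_tags	6298
fungal_gene_count	9440
diploid_relative_gene_count	41000
ploidy_factor	3
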