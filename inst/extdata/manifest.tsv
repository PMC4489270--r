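genome_id	species	taxon	subtaxon
g1	Homo_sapiens	Animals	Vertebrates
g2	Mus_musculus	Animals	Vertebrates
g3	Saccharomyces_cerevisiae	Fungi	Ascomycetes
g4	Arabidopsis_thaliana	Plants	LandPlants
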