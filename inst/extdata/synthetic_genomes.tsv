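genome_id	taxon_class	genus	species	habitat
G0001	Flavobacteriia	Flavobacterium	Flavobacterium sp0001	marine
G0002	Bacteroidia	Prevotella	Prevotella sp0002	gut
G0003	Flavobacteriia	Zobellia	Zobellia sp0003	marine
G0004	Flavobacteriia	Polaribacter	Polaribacter sp0004	marine
G0005	Cytophagia	Spirosoma	Spirosoma sp0005	soil
G0006	Cytophagia	Spirosoma	Spirosoma sp0006	soil
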