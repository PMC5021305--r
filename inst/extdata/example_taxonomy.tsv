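taxon_id	rank	parent_id	guild	tags
Animalia	kingdom	NA	other
Arthropoda	phylum	Animalia	other
Insecta	class	Arthropoda	other
Coleoptera	order	Insecta	other
Dermaptera	order	Insecta	other
Lepidoptera	order	Insecta	other
Hemiptera	order	Insecta	other
Hymenoptera	order	Insecta	other
Coccinellidae	family	Coleoptera	other
Coccinellini	tribe	Coccinellidae	other
Harmonia	genus	Coccinellini	other
Harmonia_axyridis	species	Harmonia	focal_predator
Cycloneda	genus	Coccinellini	other
Cycloneda_sanguinea	species	Cycloneda	focal_predator
Hippodamia	genus	Coccinellini	other
Hippodamia_convergens	species	Hippodamia	focal_predator
Coleomegilla	genus	Coccinellini	other
Coleomegilla_maculata	species	Coleomegilla	other_predator
Coccinella	genus	Coccinellini	other
Coccinella_septempunctata	species	Coccinella	other_predator
Forficulidae	family	Dermaptera	other
Doru	genus	Forficulidae	other
Doru_luteipes	species	Doru	focal_predator
Anthocoridae	family	Hemiptera	other
Orius_insidiosus	species	Anthocoridae	other_predator
Pentatomidae	family	Hemiptera	other
Euschistus	genus	Pentatomidae	herbivore
Noctuidae	family	Lepidoptera	other
Spodoptera	genus	Noctuidae	other
Spodoptera_frugiperda	species	Spodoptera	herbivore
Helicoverpa	genus	Noctuidae	herbivore
Plutellidae	family	Lepidoptera	other
Plutella	genus	Plutellidae	other
Plutella_xylostella	species	Plutella	herbivore
Aphididae	family	Hemiptera	herbivore
Aphis	genus	Aphididae	herbivore
Aphis_gossypii	species	Aphis	herbivore
Ichneumonoidea	superfamily	Hymenoptera	other
Braconidae	family	Ichneumonoidea	other
Aphidiinae	subfamily	Braconidae	parasitoid	aphid_parasitoid
Aphidius	genus	Aphidiinae	parasitoid	aphid_parasitoid
Euphorinae	subfamily	Braconidae	other
Dinocampus	genus	Euphorinae	other
Dinocampus_coccinellae	species	Dinocampus	parasitoid	coccinellid_parasitoid
Chalcidoidea	superfamily	Hymenoptera	parasitoid
Bacteria	kingdom	NA	other
Proteobacteria	phylum	Bacteria	other
Hamiltonella	genus	Proteobacteria	symbiont	aphid_specific_symbiont
Regiella	genus	Proteobacteria	other
Regiella_insecticola	species	Regiella	symbiont	aphid_specific_symbiont
Serratia	genus	Proteobacteria	other
Serratia_symbiotica	species	Serratia	symbiont	aphid_specific_symbiont
Arsenophonus	genus	Proteobacteria	symbiont
Buchnera	genus	Proteobacteria	symbiont	aphid_specific_symbiont
Spiroplasma	genus	Bacteria	symbiont
Wolbachia	genus	Proteobacteria	symbiont
Rickettsia	genus	Proteobacteria	symbiont
Rickettsiella	genus	Proteobacteria	symbiont
Blattabacterium	genus	Bacteria	symbiont
Fungi	kingdom	NA	other
Nosema	genus	Fungi	symbiont
Ascomycota	phylum	Fungi	fungus
Basidiomycota	phylum	Fungi	fungus
Plantae	kingdom	NA	other
Spermatophyta	phylum	Plantae	plant
Streptophyta	phylum	Plantae	plant
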