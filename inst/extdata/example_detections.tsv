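predator_id	db_id	marker_class	taxon_id	rank	read_count
Cycloneda_sanguinea	mito	insect_mitogenome	Doru_luteipes	species	3
Cycloneda_sanguinea	mito	insect_mitogenome	Harmonia_axyridis	species	3
Cycloneda_sanguinea	cox1	cox1_barcode	Harmonia_axyridis	species	4
Cycloneda_sanguinea	parasitoid	parasitoid_markers	Chalcidoidea	superfamily	5
Cycloneda_sanguinea	bacterial	bacterial_genome	Hamiltonella	genus	20
Cycloneda_sanguinea	bacterial	bacterial_genome	Spiroplasma	genus	1
Cycloneda_sanguinea	rrna	rrna	Ascomycota	phylum	1
Cycloneda_sanguinea	rrna	rrna	Spermatophyta	phylum	1
Hippodamia_convergens	mito	insect_mitogenome	Dinocampus_coccinellae	species	58
Hippodamia_convergens	mito	insect_mitogenome	Coleomegilla_maculata	species	57
Hippodamia_convergens	mito	insect_mitogenome	Harmonia_axyridis	species	27
Hippodamia_convergens	mito	insect_mitogenome	Spodoptera_frugiperda	species	18
Hippodamia_convergens	mito	insect_mitogenome	Orius_insidiosus	species	15
Hippodamia_convergens	mito	insect_mitogenome	Coccinella_septempunctata	species	11
Hippodamia_convergens	mito	insect_mitogenome	Euschistus	genus	6
Hippodamia_convergens	mito	insect_mitogenome	Helicoverpa	genus	6
Hippodamia_convergens	cox1	cox1_barcode	Dinocampus_coccinellae	species	2
Hippodamia_convergens	parasitoid	parasitoid_markers	Chalcidoidea	superfamily	19
Hippodamia_convergens	parasitoid	parasitoid_markers	Aphidiinae	subfamily	20
Hippodamia_convergens	bacterial	bacterial_genome	Regiella_insecticola	species	88
Hippodamia_convergens	bacterial	bacterial_genome	Rickettsia	genus	13
Hippodamia_convergens	bacterial	bacterial_genome	Wolbachia	genus	1
Hippodamia_convergens	bacterial	bacterial_genome	Serratia	genus	8013
Hippodamia_convergens	rrna	rrna	Ascomycota	phylum	13
Hippodamia_convergens	rrna	rrna	Spermatophyta	phylum	1
Harmonia_axyridis	mito	insect_mitogenome	Doru_luteipes	species	8
Harmonia_axyridis	mito	insect_mitogenome	Aphis_gossypii	species	5
Harmonia_axyridis	cox1	cox1_barcode	Aphis	genus	2
Harmonia_axyridis	aphid_genome	nuclear_genome	Aphis_gossypii	species	5
Harmonia_axyridis	parasitoid	parasitoid_markers	Chalcidoidea	superfamily	125
Harmonia_axyridis	parasitoid	parasitoid_markers	Aphidiinae	subfamily	35
Harmonia_axyridis	bacterial	bacterial_genome	Regiella_insecticola	species	233
Harmonia_axyridis	bacterial	bacterial_genome	Hamiltonella	genus	29
Harmonia_axyridis	bacterial	bacterial_genome	Rickettsiella	genus	12
Harmonia_axyridis	bacterial	bacterial_genome	Spiroplasma	genus	12
Harmonia_axyridis	bacterial	bacterial_genome	Wolbachia	genus	12
Harmonia_axyridis	bacterial	bacterial_genome	Arsenophonus	genus	6
Harmonia_axyridis	bacterial	bacterial_genome	Serratia	genus	16814
Harmonia_axyridis	bacterial	bacterial_genome	Serratia_symbiotica	species	5
Harmonia_axyridis	rrna	rrna	Ascomycota	phylum	3
Harmonia_axyridis	rrna	rrna	Spermatophyta	phylum	1
Harmonia_axyridis	rrna	rrna	Streptophyta	phylum	1
Doru_luteipes	mito	insect_mitogenome	Plutella_xylostella	species	16
Doru_luteipes	mito	insect_mitogenome	Harmonia_axyridis	species	7
Doru_luteipes	mito	insect_mitogenome	Aphididae	family	2
Doru_luteipes	cox1	cox1_barcode	Plutella_xylostella	species	1
Doru_luteipes	parasitoid	parasitoid_markers	Aphidius	genus	1
Doru_luteipes	bacterial	bacterial_genome	Spiroplasma	genus	1419
Doru_luteipes	bacterial	bacterial_genome	Rickettsia	genus	642
Doru_luteipes	bacterial	bacterial_genome	Wolbachia	genus	640
Doru_luteipes	bacterial	bacterial_genome	Nosema	genus	263
Doru_luteipes	bacterial	bacterial_genome	Serratia	genus	11095
Doru_luteipes	bacterial	bacterial_genome	Serratia_symbiotica	species	29
Doru_luteipes	bacterial	bacterial_genome	Regiella_insecticola	species	21
Doru_luteipes	bacterial	bacterial_genome	Arsenophonus	genus	9
Doru_luteipes	bacterial	bacterial_genome	Blattabacterium	genus	6
Doru_luteipes	bacterial	bacterial_genome	Hamiltonella	genus	3
Doru_luteipes	rrna	rrna	Spermatophyta	phylum	128
Doru_luteipes	rrna	rrna	Streptophyta	phylum	2
Doru_luteipes	rrna	rrna	Ascomycota	phylum	570
Doru_luteipes	rrna	rrna	Basidiomycota	phylum	7
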