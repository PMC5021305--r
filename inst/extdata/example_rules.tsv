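trigger_tag	implied_prey_group	evidence_type
aphid_specific_symbiont	Aphididae	symbiont
aphid_parasitoid	Aphididae	parasitoid
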