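# Per-database matching thresholds: minimum alignment overlap and percent
# identity, E-value ceiling, target cap, and (for rRNA) the host-lineage
# exclusion rank.
mito:
  min_identity: 98
  min_overlap: 225
  max_evalue: 1.0e-5
  max_targets: 3
  algorithm_hint: blastn_like
cox1:
  min_identity: 99
  min_overlap: 225
  max_evalue: 1.0e-9
  max_targets: 3
  algorithm_hint: megablast_like
aphid_genome:
  min_identity: 99
  min_overlap: 225
  max_evalue: 1.0e-9
  max_targets: 3
  algorithm_hint: megablast_like
parasitoid:
  min_identity: 99
  min_overlap: 225
  max_evalue: 1.0e-5
  max_targets: 3
  algorithm_hint: blastn_like
bacterial:
  min_identity: 95
  min_overlap: 225
  max_evalue: 1.0e-9
  max_targets: 3
  algorithm_hint: megablast_like
rrna:
  min_identity: 99
  min_overlap: 225
  max_evalue: 1.0e-5
  max_targets: 3
  algorithm_hint: blastn_like
  host_exclusion_rank: tribe
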