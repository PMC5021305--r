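# gutlink

Trophic-link inference from PCR-free shotgun sequencing of arthropod
predator gut contents.

## What it does, and for whom

Ecologists who want to know *who eats whom* in an arthropod assemblage
usually PCR-amplify a barcode from gut-content DNA. That works poorly for
generalist predators: primers pre-select the visible taxa, digested DNA
amplifies erratically, and prey closely related to the predator disappear
under the host signal. The alternative is to shotgun-sequence the total gut
DNA and identify, read by read, the tiny foreign fraction — prey, intraguild
prey, parasitoids, and prey-associated symbionts — by stringent matching
against reference databases.

`gutlink` implements that workflow as a reusable R package:

* **Read QC** — adapter clipping and mean-Phred ≥ 20 filtering
  (`qualityFilter`, `trimAdapters`, `toFasta`).
* **Matching** — a built-in seed-and-extend local aligner (k-mer seeds on
  both strands, affine-gap Smith–Waterman; match +1, mismatch −2, gap open
  5, gap extend 2) with Karlin–Altschul E-values `E = K·m·n·e^{−λS}`, plus an
  importer for standard BLAST `outfmt 6` tabular files (`alignReads`,
  `importBlastTabular`).
* **Identification** — the core filtering discipline: alignment overlap
  ≥ 225 bp and identity ≥ 98 % (insect mitogenomes) / 95 % (bacterial
  genomes) / 99 % (other databases), exclusion of reads touching masked
  regions (mitochondrial control regions, tandem repeats found by
  `detectSsrRegions`, host-shared markers), host-lineage exclusion for
  non-diagnostic rRNA, read-level host/foreign separation, and assignment of
  each surviving read to the lowest common ancestor of its near-best hits
  (`filterHits`, `excludeMasked`, `excludeHostLineage`, `separateHost`,
  `assignTaxa`, `tallyDetections`, or everything at once via
  `identifyGutContents`).
* **Network inference** — per-database detections become a qualitative
  trophic network: cross-database merging into the most specific taxon,
  direct predation edges with intraguild/extraguild typing, and *inferred*
  edges where an obligate prey associate (e.g. the aphid symbionts
  *Hamiltonella*, *Regiella insecticola*, *Serratia symbiotica*) was detected
  without prey DNA (`buildTrophicNetwork`, `summarizeNetwork`,
  `exportNetwork` to TSV/DOT/GraphML).
* **Simulation** — a scenario-based generator of host-dominated gut-content
  libraries with rare, degraded foreign templates, controlled reference
  divergences and per-read ground truth, so the whole pipeline is testable
  without sequencing data (`communityScenario`, `generateGenomes`,
  `simulateGutReads`, `scenarioFromStudyProfile`).

A thin command-line front end is installed as `exec/gutlink`
(`gutlink qc`, `gutlink match`, `gutlink identify`, `gutlink network`).

## Worked example

The package bundles the detection tables of a four-predator field study
(three ladybirds, one earwig) as plain TSVs:

```r
library(gutlink)
ex  <- exampleGutStudy()
net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
s   <- summarizeNetwork(net, ex$detections, ex$taxonomy, ex$rules)
s$per_predator
#>             predator_id direct_links inferred_links intraguild_richness intraguild_coccinellid intraguild_other
#> 1   Cycloneda_sanguinea            2              1                   2                      1                1
#> 2 Hippodamia_convergens            8              1                   4                      3                1
#> 3     Harmonia_axyridis            2              0                   1                      0                1
#> 4         Doru_luteipes            3              0                   1                      1                0
s$pooled
#> $n_direct_links            [1] 15
#> $species_or_genus_links    [1] 14
#> $species_or_genus_pct      [1] 93
#> $linked_species_genus_taxa [1] 15
```

Reading: the four predators carry 2, 8, 2 and 3 direct prey links; two
predators additionally carry one *inferred* aphid link each, supported only
by aphid-specific symbiont reads (20 and 88 reads) — aphid consumption
without surviving aphid DNA. 14 of the 15 direct links (93 %) resolve to
species or genus, and 15 distinct species/genus taxa carry some trophic
linkage. Every predator shows intraguild predation; the richest gut
(*Hippodamia convergens*) contains three other ladybird species plus one
non-coccinellid predator.

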