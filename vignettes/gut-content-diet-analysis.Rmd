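---
title: "PCR-free diet analysis from shotgun sequencing of predator gut contents"
author: "gutlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCR-free diet analysis from shotgun sequencing of predator gut contents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutlink)
```

## The problem

Molecular gut-content analysis of small generalist predators usually relies
on PCR of a barcode marker (metabarcoding). That choice constrains the
analysis from the outset: primers determine which taxa are visible, PCR on
degraded templates skews recovery, and close relatives of the predator are
nearly impossible to detect against the overwhelming excess of host DNA.
An alternative is to shotgun-sequence the total DNA of the gut and ask, read
by read, whether a sequence is host or foreign — no primers, no marker
choice, any organism with a reference sequence is in principle detectable:
prey, intraguild prey, parasitoids, and the microbiome that travels with the
prey.

The catch is that foreign DNA is rare (tens to hundreds of reads among
millions) and digested (short templates), so identification must be
stringent enough that a handful of matching reads can be trusted. `gutlink`
implements that identification discipline end to end, plus the inference
step that turns per-database detections into a qualitative trophic network.

## The method

The pipeline mirrors the structure of shotgun diet studies:

1. **Read QC** (`qualityFilter()`, `trimAdapters()`): reads keep their base
   calls untouched; a read survives iff its mean Phred score is at least 20.
   The cited pre-processing convention ("minimum Phred quality score of 20")
   does not state whether the bound is per-base or per-read; we adopt the
   mean-quality reading, which is the conventional usage of the tool the
   convention comes from, and provide a per-base 3' trim as an explicit
   alternative (`mode = "trim3"`).

2. **Matching** (`alignReads()`): a seed-and-extend local aligner (12-mer
   seeds on both strands, affine-gap Smith–Waterman extension over the
   seed-defined window; match +1, mismatch −2, gap open 5, gap extend 2 —
   the stringent nucleotide-search defaults). E-values follow the
   Karlin–Altschul form `E = K·m·n·exp(−λS)` with λ solved from the scoring
   scheme (`alignmentLambda()`) and K a configurable constant (default 0.1):
   the ceilings used in this field (1e−5 for BLASTn-style searches, 1e−9 for
   MegaBLAST-style ones) sit so far from the scores of genuine ≥225 bp hits
   that the exact K is immaterial. No query masking is performed (the
   "no dust" convention), and at most `max_targets` (default 3) subjects are
   kept per read. Standard BLAST outfmt-6 files can be imported instead
   (`importBlastTabular()`), so the package's filtering and network stages
   also serve pipelines that ran the matching elsewhere.

3. **Identification** (`filterHits()`, `excludeMasked()`,
   `excludeHostLineage()`, `separateHost()`, `assignTaxa()`): the core of
   the method. A hit survives iff its alignment spans at least 225 columns
   *and* its identity meets the database's threshold — 98% for insect
   mitogenomes, 95% for bacterial genomes, 99% for everything else. All
   bounds are inclusive ("minimum overlap of 225 bp" reads naturally as
   ≥ 225), and overlap is measured as alignment columns (the outfmt-6
   `length` field), matching what such filters are applied to in practice.
   Reads touching masked regions — mitochondrial control regions (supplied
   as explicit BED annotations, since they are curated knowledge), tandem
   repeats (`detectSsrRegions()`, which automates the manual SSR check), or
   markers shared with the host — are discarded with ≥1 bp overlap
   sufficing, the conservative reading. For rRNA-class markers any hit
   whose taxon shares an ancestor with the focal predator at or below a
   configurable rank (default tribe) is removed: within that clade the
   marker cannot distinguish prey from predator, generalizing the original
   rule that was stated for one predator tribe.

4. **Host separation and LCA assignment**: reads matching the focal
   predator's own lineage are host evidence; a read with both host and
   foreign hits goes to the side with the better raw score, ties to host
   (a read that matches the host equally well is not prey evidence).
   Surviving foreign reads are assigned per database to the lowest common
   ancestor of all hits within 98% of the best raw score
   (`score_tolerance = 0.98`). The tolerance automates the judgment call
   "the matched region is identical in closely related species, so report
   the rank at which the match is reliable": equal-best hits to two
   congeners collapse to the genus, while a clearly better single hit keeps
   its species. 0.98 was chosen to equal the identity margin the mitogenome
   threshold itself tolerates; it is exposed as a parameter.

5. **Network inference** (`buildTrophicNetwork()`): per-database detections
   become a qualitative trophic network. Detections of the same lineage
   across the insect databases (mitogenome, cox1 barcode, nuclear genome)
   merge into the most specific taxon with summed read support — a genus-
   level barcode match and a species-level mitogenome match are one prey,
   not two. Each merged insect taxon yields a direct predation edge, classed
   intraguild when the prey is itself in the configured predator guild list
   (guild membership is ecological knowledge and therefore config input,
   not something computable from reads). Detections of taxa tagged as
   obligate associates of a prey group (aphid-specific symbionts such as
   *Hamiltonella*, *Regiella insecticola*, *Serratia symbiotica*; aphid
   parasitoids) imply consumption of that group: if no direct edge already
   reaches the group, one *inferred* edge is emitted, supported by the
   symbiont read counts (parasitoid detections corroborate but do not
   count as biomass-flow support, since a parasitoid read may equally
   reflect predation on the free-living adult). Species-level parasitoids
   recovered from insect markers are emitted as direct edges with an
   explicit uncertainty note — reads cannot distinguish eating a parasitoid
   from carrying one. Supra-genus parasitoid detections (e.g. a superfamily
   resolved from a conserved rRNA region) never form direct edges.

## Worked example

The package bundles the detection tables of a four-predator field study
(three ladybirds and one earwig from a tropical agroecosystem) as plain
TSVs:

```{r example}
ex <- exampleGutStudy()
net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
net
s <- summarizeNetwork(net, ex$detections, ex$taxonomy, ex$rules)
s$per_predator
s$pooled
```

The direct link counts per predator (2, 8, 2, 3), the two inferred aphid
edges, the pooled resolution (14 of 15 direct links at species or genus,
93%) and the 15 species/genus taxa carrying a trophic linkage are computed
by the package from the bundled tables; the acceptance script
(`scripts/acceptance.R`) recomputes them from scratch.

## The simulator: what it emulates, and what it does not

`communityScenario()` + `simulateGutReads()` generate libraries with the
statistical structure this analysis faces:

* a dominant host nuclear background (modeled as a 1 Mb stand-in sequence —
  its only role is to be unmatchable by the reference databases, so its
  length only needs to dwarf the markers);
* host mitochondrial DNA at a set fraction of reads (typically 0.07–0.7%;
  the constructor warns outside that band);
* tens to hundreds of foreign reads per multi-million-read library, at
  per-taxon fractions; `scenarioFromStudyProfile()` presets these to the
  observed per-taxon counts of the four-predator study;
* degraded foreign templates: template length is a mixture of an intact
  fraction (default 0.5) at full read length and a truncated normal
  (mean 120, sd 40, hard max 200 bp) for digested fragments. Digested DNA
  is expected to be ≤200 bp, which a 225 bp overlap filter can never pass —
  the mixture makes explicit that only the intact tail of the template
  distribution is detectable, which is exactly the low-recovery regime the
  method operates in;
* substitution-only sequencing errors at 0.2% per base with Phred strings
  consistent with that rate (Q27), the dominant error mode of the platform
  emulated; indels in the *references* can be exercised through the test
  oracles instead;
* reference-only "relative" taxa at a controlled divergence (default 5%,
  straddling the 98% identity threshold) that join the databases without
  emitting reads — these power the identity-threshold sweep
  (`thresholdSweep()`), reproducing the direction of the 90%-vs-98%
  comparison: lower thresholds admit more reads and more (spurious) taxa.

Divergence targets are realized by mutating a common ancestor per lineage
group (star model); two-member groups are solved exactly from
`2p − (4/3)p² = d`, larger groups by bounded least squares, and the
realized matrix is returned for inspection. Pairs of unrelated members are
generated independently (≈75% divergence), which is the attainable and
honest model for, say, a mitogenome versus a bacterial genome.

The simulator does *not* model PCR duplicates, GC bias, flow-cell
artifacts, chimeras, contamination, or time-dependent post-ingestion decay
(decay enters only implicitly through the read fractions). Passing the
round-trip tests therefore demonstrates that the identification logic is
correct and calibrated, not that real libraries are free of contamination
or reference gaps — on real data the reference databases remain the
limiting factor.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package (interval
  arithmetic safety); 1-based inclusive coordinates appear only at the
  outfmt-6 import/export boundary, where `sstart > send` encodes the minus
  strand.
* Seed clusters are extended only when their seeds span at least one seed
  length of the read: overlapping k-mers arising from a single chance
  shared word are not independent evidence, and alignments too short to
  pass the 225 bp overlap filter are not worth computing. On simulated
  reads at ≤5% divergence the seed-and-extend score equals the exact
  dynamic-programming optimum (checked against an independent DP
  implementation in the test suite).
* Ties everywhere break conservatively: equal host/foreign scores go to
  host; equal-score subjects are ordered by identity then lexicographic id;
  the LCA of a duplicated taxon is that taxon.
* `max_targets` counts distinct subject sequences, keeping only the best
  local alignment per subject, and applies to every database (stated
  originally only for the BLASTn-run databases; uniformity is simpler and
  it is configurable).
* An ancestor-level detection folds into a descendant only when the
  descendant is unique among that predator's detections; an ambiguous
  ancestor (two maximal descendants) stays separate rather than guessing.
* Degenerate inputs are defined, not special-cased: zero reads simulate to
  empty outputs, empty hit tables filter to empty tables, an empty network
  exports a valid document.
* Test and acceptance problem sizes: property suites run at 10³ random
  cases; the round-trip uses one-million-read libraries per predator, the
  scale at which per-taxon read counts match the study's libraries after
  scaling and the whole suite still runs on a laptop-class single core.

## Known limitations

* The built-in aligner is a desk-scale tool (reads ≤ a few hundred bp,
  references up to tens of Mb); genome-scale searches should use a
  dedicated search tool and enter through `importBlastTabular()`.
* E-values use a fixed K rather than the full tabulated Karlin–Altschul
  parameters; with the E-value ceilings used here this affects no decision.
* LCA assignment requires all tied taxa to share a rooted lineage; taxa
  from disconnected taxonomies (e.g. an uncurated reference) yield an NA
  assignment, which is reported rather than guessed.
* The inferred-edge rule is qualitative by design: symbiont read counts
  support the presence of a link, never its strength, and read counts are
  nowhere interpreted as biomass.
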