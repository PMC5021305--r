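Package: gutlink
Title: Trophic-Link Inference from Shotgun Sequencing of Predator Gut Contents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: PCR-free diet analysis for arthropod predators from shotgun
    sequencing of gut-content DNA. Reads are quality-filtered, matched against
    multiple taxonomically annotated reference databases with a built-in
    seed-and-extend local aligner (or imported BLAST tabular hits), and
    identified as host or foreign DNA by stringent alignment-length and
    percent-identity thresholds with masked-region and host-lineage
    exclusions. Surviving reads are assigned to the lowest reliably
    identifiable taxon by a score-tolerant lowest-common-ancestor rule, and
    per-database detections are combined into a qualitative trophic network
    with direct predation edges and indirect edges inferred from prey-specific
    symbionts and parasitoids. A scenario-based simulator generates
    host-dominated gut-content libraries with rare, degraded foreign templates
    and truth tables so the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
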