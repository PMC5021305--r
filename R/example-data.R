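# Bundled worked example: detection tables from a four-predator field study.

#' Worked-example detection tables from a four-predator gut-content study
#'
#' Loads the package's bundled example: per-database foreign-taxon
#' detections from shotgun gut-content libraries of three coccinellids
#' (*Cycloneda sanguinea*, *Hippodamia convergens*, *Harmonia axyridis*) and
#' one earwig (*Doru luteipes*) co-occurring in a tropical agroecosystem,
#' together with the matching taxonomy/guild table and the
#' symbiont/parasitoid association rules. The fixture carries the read
#' counts recovered against six reference databases (insect mitogenomes,
#' cox1 barcodes, aphid nuclear genomes, parasitoid markers, bacterial
#' genomes, rRNA) and is the input of the network-building worked example in
#' the vignette.
#'
#' @return list with `detections` (data.frame), `taxonomy`
#'   ([Taxonomy][readTaxonomy()]) and `rules` (data.frame).
#' @examples
#' ex <- exampleGutStudy()
#' net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
#' summarizeNetwork(net, ex$detections, ex$taxonomy, ex$rules)$pooled
#' @export
exampleGutStudy <- function() {
  dir <- system.file("extdata", package = "gutlink")
  list(
    detections = read.delim(file.path(dir, "example_detections.tsv"),
                            stringsAsFactors = FALSE),
    taxonomy = readTaxonomy(file.path(dir, "example_taxonomy.tsv")),
    rules = readAssociationRules(file.path(dir, "example_rules.tsv"))
  )
}
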