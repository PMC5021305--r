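# Taxonomy table: lineages, ranks, guilds and association tags.

#' @rdname readTaxonomy
#' @export
setClass("Taxonomy", representation(table = "data.frame"))

setValidity("Taxonomy", function(object) {
  tab <- object@table
  need <- c("taxon_id", "rank", "parent_id", "guild", "tags")
  msg <- character()
  if (!all(need %in% names(tab)))
    return(paste("taxonomy table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$taxon_id))
    msg <- c(msg, "duplicated taxon_id")
  if (!all(tab$rank %in% RANK_LEVELS))
    msg <- c(msg, paste("unknown ranks:",
                        paste(setdiff(tab$rank, RANK_LEVELS), collapse = ", ")))
  known <- c(tab$taxon_id, NA)
  if (!all(tab$parent_id %in% known))
    msg <- c(msg, "parent_id values must be taxon_ids or NA")
  if (length(msg)) msg else TRUE
})

GUILDS <- c("focal_predator", "other_predator", "herbivore", "parasitoid",
            "symbiont", "plant", "fungus", "other")

#' Read or construct a taxonomy table
#'
#' The taxonomy is a flat table with one row per taxon: `taxon_id`, `rank`
#' (one of species, genus, tribe, subfamily, family, superfamily, order,
#' class, phylum, kingdom), `parent_id` (NA for roots), `guild` (ecological
#' role used for network typing) and `tags` (comma-separated association
#' labels such as `aphid_specific_symbiont`).
#'
#' @param path TSV file with the columns above.
#' @param table alternatively, a data.frame with those columns.
#' @return A `Taxonomy` object.
#' @export
readTaxonomy <- function(path = NULL, table = NULL) {
  if (is.null(table)) {
    table <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$guild)) table$guild <- "other"
  if (is.null(table$tags)) table$tags <- ""
  table$tags[is.na(table$tags)] <- ""
  new("Taxonomy", table = table)
}

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy with", nrow(object@table), "taxa;",
      sum(is.na(object@table$parent_id)), "root(s)\n")
})

#' @rdname taxonomy-queries
#' @export
taxonomyTable <- function(taxonomy) taxonomy@table

rankLevel <- function(rank) match(rank, RANK_LEVELS)

#' Taxonomy queries: lineage, rank, LCA, descent
#'
#' `taxonLineage()` returns the ordered ancestor chain of a taxon, starting at
#' the taxon itself and ending at its root. `taxonRank()` returns rank labels.
#' `lcaTaxon()` returns the lowest (most specific) common ancestor of a set of
#' taxa, the rule used to assign a read conservatively when several reference
#' matches are equally good. `isDescendant()` tests whether `taxon_id` equals
#' `ancestor` or lies below it.
#'
#' @param taxonomy a [Taxonomy][readTaxonomy()] object.
#' @param taxon_id,taxon_ids taxon identifier(s).
#' @param ancestor candidate ancestor taxon id.
#' @return `taxonLineage()`: character vector; `lcaTaxon()`: list with
#'   `taxon_id` and `rank` (both NA when the taxa share no ancestor);
#'   `isDescendant()`: logical.
#' @name taxonomy-queries
NULL

#' @rdname taxonomy-queries
#' @export
taxonLineage <- function(taxonomy, taxon_id) {
  tab <- taxonomy@table
  parent <- setNames(tab$parent_id, tab$taxon_id)
  out <- character()
  cur <- taxon_id
  while (!is.na(cur) && cur %in% names(parent)) {
    if (cur %in% out) stop("taxonomy cycle at taxon: ", cur)
    out <- c(out, cur)
    cur <- parent[[cur]]
  }
  if (length(out) == 0L) stop("unknown taxon_id: ", taxon_id)
  out
}

#' @rdname taxonomy-queries
#' @export
taxonRank <- function(taxonomy, taxon_id) {
  tab <- taxonomy@table
  tab$rank[match(taxon_id, tab$taxon_id)]
}

#' @rdname taxonomy-queries
#' @export
taxonGuild <- function(taxonomy, taxon_id) {
  tab <- taxonomy@table
  tab$guild[match(taxon_id, tab$taxon_id)]
}

#' @rdname taxonomy-queries
#' @export
taxonTags <- function(taxonomy, taxon_id) {
  tab <- taxonomy@table
  raw <- tab$tags[match(taxon_id, tab$taxon_id)]
  if (is.na(raw) || !nzchar(raw)) return(character())
  trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
}

#' @rdname taxonomy-queries
#' @export
lcaTaxon <- function(taxonomy, taxon_ids) {
  taxon_ids <- unique(taxon_ids)
  lineages <- lapply(taxon_ids, taxonLineage, taxonomy = taxonomy)
  common <- Reduce(intersect, lineages)
  if (length(common) == 0L)
    return(list(taxon_id = NA_character_, rank = NA_character_))
  # intersect() preserves the order of the first lineage (self -> root), so
  # the first common entry is the deepest shared ancestor.
  list(taxon_id = common[[1]], rank = taxonRank(taxonomy, common[[1]]))
}

#' @rdname taxonomy-queries
#' @export
isDescendant <- function(taxonomy, taxon_id, ancestor) {
  vapply(taxon_id, function(t) ancestor %in% taxonLineage(taxonomy, t),
         logical(1), USE.NAMES = FALSE)
}

#' Does a taxon share an ancestor with another at or below a given rank?
#'
#' Used for host-lineage exclusion of non-diagnostic markers: an rRNA hit
#' whose subject taxon shares, say, a tribe-level ancestor with the focal
#' predator cannot distinguish prey from predator and is discarded.
#'
#' @inheritParams taxonomy-queries
#' @param a,b taxon ids.
#' @param rank rank label; ancestors at this rank or more specific count.
#' @return logical.
#' @export
sharesAncestorAtOrBelow <- function(taxonomy, a, b, rank) {
  lev <- rankLevel(rank)
  if (is.na(lev)) stop("unknown rank label: ", rank)
  common <- intersect(taxonLineage(taxonomy, a), taxonLineage(taxonomy, b))
  if (length(common) == 0L) return(FALSE)
  any(rankLevel(taxonRank(taxonomy, common)) <= lev)
}

#' Cross-check reference databases against a taxonomy table
#'
#' Report-only consistency audit of a database registry: taxon ids used by
#' database sequences that the taxonomy cannot resolve, parent/child rank
#' inversions (a parent's rank must be strictly less specific than its
#' child's), association tags outside the rule vocabulary, and tags placed on
#' taxa whose lineage is implausible for the tag (e.g. an aphid-specific
#' symbiont label on a non-bacterial taxon).
#'
#' @param databases list of [ReferenceDatabase-class] objects (may be empty).
#' @param taxonomy a [Taxonomy][readTaxonomy()] object.
#' @param tag_vocabulary valid association tags.
#' @param tag_clades named character; for each tag, a clade that tagged taxa
#'   are expected to belong to.
#' @return data.frame with columns `type` and `detail`; zero rows iff the
#'   registry is consistent.
#' @export
validateTaxonomy <- function(databases, taxonomy,
                             tag_vocabulary = c("aphid_specific_symbiont",
                                                "aphid_parasitoid",
                                                "coccinellid_parasitoid"),
                             tag_clades = c(aphid_specific_symbiont = "Bacteria",
                                            aphid_parasitoid = "Hymenoptera",
                                            coccinellid_parasitoid = "Hymenoptera")) {
  tab <- taxonomy@table
  report <- list()
  note <- function(type, detail)
    report[[length(report) + 1L]] <<- data.frame(type = type, detail = detail,
                                                 stringsAsFactors = FALSE)
  if (is(databases, "ReferenceDatabase")) databases <- list(databases)
  for (db in databases) {
    missing <- setdiff(unique(seqTaxon(db)), tab$taxon_id)
    for (m in missing)
      note("unresolvable_taxon", paste0(dbId(db), ": ", m))
  }
  # rank consistency: parent strictly higher (less specific) than child
  pr <- rankLevel(tab$rank[match(tab$parent_id, tab$taxon_id)])
  cr <- rankLevel(tab$rank)
  bad <- which(!is.na(pr) & pr <= cr)
  for (i in bad)
    note("rank_inconsistency",
         paste0(tab$taxon_id[i], " (", tab$rank[i], ") under ",
                tab$parent_id[i], " (",
                tab$rank[match(tab$parent_id[i], tab$taxon_id)], ")"))
  for (i in seq_len(nrow(tab))) {
    tags <- taxonTags(taxonomy, tab$taxon_id[i])
    for (tg in tags) {
      if (!tg %in% tag_vocabulary) {
        note("unknown_tag", paste0(tab$taxon_id[i], ": ", tg))
      } else if (tg %in% names(tag_clades)) {
        clade <- tag_clades[[tg]]
        if (clade %in% tab$taxon_id &&
            !clade %in% taxonLineage(taxonomy, tab$taxon_id[i]))
          note("tag_clade_mismatch",
               paste0(tab$taxon_id[i], ": ", tg, " expected within ", clade))
      }
    }
  }
  if (length(report)) do.call(rbind, report)
  else data.frame(type = character(), detail = character(),
                  stringsAsFactors = FALSE)
}
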