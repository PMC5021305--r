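# S4 classes shared across the package.

MARKER_CLASSES <- c("insect_mitogenome", "cox1_barcode", "nuclear_genome",
                    "parasitoid_markers", "rrna", "bacterial_genome")

# Ranks ordered from most to least specific; exclusion/LCA logic compares
# positions in this vector ("at or below rank r" means position <= match(r)).
RANK_LEVELS <- c("species", "genus", "tribe", "subfamily", "family",
                 "superfamily", "order", "class", "phylum", "kingdom")

MASK_REASONS <- c("control_region", "ssr", "shared_marker")

#' @rdname MatchPolicy
#' @export
setClass("MatchPolicy", representation(
  min_identity = "numeric",
  min_overlap = "numeric",
  max_evalue = "numeric",
  max_targets = "integer",
  algorithm_hint = "character",
  host_exclusion_rank = "character"
))

setValidity("MatchPolicy", function(object) {
  msg <- character()
  if (!(object@min_identity > 0 && object@min_identity <= 100))
    msg <- c(msg, "min_identity must be in (0, 100]")
  if (object@min_overlap <= 0)
    msg <- c(msg, "min_overlap must be > 0")
  if (object@max_targets < 1L)
    msg <- c(msg, "max_targets must be >= 1")
  if (!object@algorithm_hint %in% c("blastn_like", "megablast_like"))
    msg <- c(msg, "algorithm_hint must be 'blastn_like' or 'megablast_like'")
  if (!is.na(object@host_exclusion_rank) &&
      !object@host_exclusion_rank %in% RANK_LEVELS)
    msg <- c(msg, "host_exclusion_rank must be a known rank or NA")
  if (length(msg)) msg else TRUE
})

#' Per-database matching and filtering policy
#'
#' Bundles the acceptance thresholds applied to alignment hits from one
#' reference database: minimum percent identity and alignment overlap
#' (columns, including gaps), the E-value ceiling and maximum number of
#' distinct subject sequences retained per read, plus an optional host-lineage
#' exclusion rank for markers (such as rRNA) that cannot distinguish prey from
#' the focal predator below some taxonomic level.
#'
#' Defaults follow stringent shotgun diet-analysis practice: 225 bp minimum
#' overlap everywhere, 98% identity for insect mitogenomes, 95% for bacterial
#' genomes and 99% for all other databases (see [defaultPolicies()]).
#'
#' @param min_identity minimum percent identity, in (0, 100]; inclusive bound.
#' @param min_overlap minimum alignment length in columns (bp); inclusive.
#' @param max_evalue E-value ceiling for hits.
#' @param max_targets maximum distinct subject sequences kept per read.
#' @param algorithm_hint `"blastn_like"` or `"megablast_like"`.
#' @param host_exclusion_rank rank at or below which a shared ancestor with
#'   the focal predator disqualifies a hit (NA = no exclusion).
#' @return A `MatchPolicy` object.
#' @examples
#' MatchPolicy(min_identity = 98, min_overlap = 225)
#' @export
MatchPolicy <- function(min_identity = 99, min_overlap = 225,
                        max_evalue = 1e-5, max_targets = 3,
                        algorithm_hint = "blastn_like",
                        host_exclusion_rank = NA_character_) {
  new("MatchPolicy",
      min_identity = as.numeric(min_identity),
      min_overlap = as.numeric(min_overlap),
      max_evalue = as.numeric(max_evalue),
      max_targets = as.integer(max_targets),
      algorithm_hint = algorithm_hint,
      host_exclusion_rank = as.character(host_exclusion_rank))
}

setMethod("show", "MatchPolicy", function(object) {
  cat("MatchPolicy: identity >=", object@min_identity,
      "| overlap >=", object@min_overlap, "bp",
      "| E <", format(object@max_evalue),
      "| max targets", object@max_targets,
      "|", object@algorithm_hint, "\n")
  if (!is.na(object@host_exclusion_rank))
    cat("  host-lineage exclusion at or below rank:",
        object@host_exclusion_rank, "\n")
})

#' @rdname loadDatabase
#' @export
setClass("ReferenceDatabase", representation(
  db_id = "character",
  marker_class = "character",
  sequences = "DNAStringSet",
  seq_taxon = "character",   # named by seq_id
  policy = "MatchPolicy",
  masked = "data.frame"      # seq_id, start, end (0-based half-open), reason
))

setValidity("ReferenceDatabase", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (length(object@sequences) == 0L)
    msg <- c(msg, "database has no sequences")
  if (anyDuplicated(ids))
    msg <- c(msg, paste("duplicated seq_id:",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!identical(sort(ids), sort(names(object@seq_taxon))))
    msg <- c(msg, "seq_taxon must be named by exactly the sequence ids")
  if (!object@marker_class %in% MARKER_CLASSES)
    msg <- c(msg, paste("unknown marker_class:", object@marker_class))
  bad <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)[, "other", drop = TRUE]
  if (any(bad > 0))
    msg <- c(msg, paste("sequences contain letters outside {A,C,G,T,N}:",
                        paste(ids[bad > 0], collapse = ", ")))
  m <- object@masked
  if (nrow(m)) {
    need <- c("seq_id", "start", "end", "reason")
    if (!all(need %in% names(m))) {
      msg <- c(msg, "masked must have columns seq_id, start, end, reason")
    } else {
      if (!all(m$seq_id %in% ids))
        msg <- c(msg, "masked regions refer to unknown seq_id")
      len <- Biostrings::width(object@sequences)[match(m$seq_id, ids)]
      if (any(m$start < 0 | m$start >= m$end | m$end > len, na.rm = TRUE))
        msg <- c(msg, "masked intervals must satisfy 0 <= start < end <= seq length")
      if (!all(m$reason %in% MASK_REASONS))
        msg <- c(msg, "masked reasons must be control_region, ssr or shared_marker")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceDatabase", function(object) {
  cat("ReferenceDatabase '", object@db_id, "' (", object@marker_class, ")\n",
      sep = "")
  cat(" ", length(object@sequences), "sequences,",
      sum(Biostrings::width(object@sequences)), "bp,",
      length(unique(object@seq_taxon)), "taxa,",
      nrow(object@masked), "masked regions\n")
  show(object@policy)
})

#' @rdname accessors
#' @export
setGeneric("dbId", function(x) standardGeneric("dbId"))
#' @rdname accessors
#' @export
setGeneric("markerClass", function(x) standardGeneric("markerClass"))
#' @rdname accessors
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))
#' @rdname accessors
#' @export
setGeneric("seqTaxon", function(x) standardGeneric("seqTaxon"))
#' @rdname accessors
#' @export
setGeneric("matchPolicy", function(x) standardGeneric("matchPolicy"))
#' @rdname accessors
#' @export
setGeneric("maskedRegions", function(x) standardGeneric("maskedRegions"))
#' @rdname accessors
#' @export
setGeneric("maskedRegions<-", function(x, value) standardGeneric("maskedRegions<-"))

#' Accessors for ReferenceDatabase
#'
#' @param x a [ReferenceDatabase-class] object.
#' @param value replacement masked-region data.frame
#'   (`seq_id`, `start`, `end`, `reason`; 0-based half-open coordinates).
#' @name accessors
#' @aliases dbId markerClass refSequences seqTaxon matchPolicy maskedRegions
NULL

#' @rdname accessors
#' @export
setMethod("dbId", "ReferenceDatabase", function(x) x@db_id)
#' @rdname accessors
#' @export
setMethod("markerClass", "ReferenceDatabase", function(x) x@marker_class)
#' @rdname accessors
#' @export
setMethod("refSequences", "ReferenceDatabase", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("seqTaxon", "ReferenceDatabase", function(x) x@seq_taxon)
#' @rdname accessors
#' @export
setMethod("matchPolicy", "ReferenceDatabase", function(x) x@policy)
#' @rdname accessors
#' @export
setMethod("maskedRegions", "ReferenceDatabase", function(x) x@masked)
#' @rdname accessors
#' @export
setMethod("maskedRegions<-", "ReferenceDatabase", function(x, value) {
  x@masked <- as.data.frame(value)
  validObject(x)
  x
})

#' @rdname readFastq
#' @export
setClass("ShotgunReads", representation(
  id = "character",
  sequence = "character",
  quality = "character"      # Phred+33 strings, same widths as sequence
))

setValidity("ShotgunReads", function(object) {
  msg <- character()
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@quality) != n)
    msg <- c(msg, "id, sequence and quality must have equal length")
  if (n) {
    if (any(nchar(object@sequence) != nchar(object@quality)))
      msg <- c(msg, "per-read sequence and quality widths differ")
  }
  if (length(msg)) msg else TRUE
})

setMethod("length", "ShotgunReads", function(x) length(x@id))

setMethod("show", "ShotgunReads", function(object) {
  n <- length(object)
  cat("ShotgunReads with", n, "reads")
  if (n) {
    w <- nchar(object@sequence)
    cat("; widths", min(w), "-", max(w),
        "; mean quality", round(mean(meanPhred(object)), 1))
  }
  cat("\n")
})

setMethod("[", "ShotgunReads", function(x, i, j, ..., drop = TRUE) {
  new("ShotgunReads", id = x@id[i], sequence = x@sequence[i],
      quality = x@quality[i])
})

#' Construct a ShotgunReads object from vectors
#'
#' @param id,sequence,quality parallel character vectors (quality in
#'   Phred+33 encoding; pass `NULL` to synthesize a uniform Q40 string).
#' @return A `ShotgunReads` object.
#' @export
shotgunReads <- function(id, sequence, quality = NULL) {
  if (is.null(quality))
    quality <- strrep(rawToChar(as.raw(33L + 40L)), nchar(sequence))
  new("ShotgunReads", id = as.character(id), sequence = toupper(sequence),
      quality = quality)
}
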