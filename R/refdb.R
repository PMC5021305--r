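# Reference-database registry: loading, policies, masked regions.

#' Default matching policies for the six database kinds
#'
#' One policy per marker class, reflecting the stringency appropriate to each
#' reference type: 225 bp minimum overlap throughout; 98% identity for insect
#' mitogenomes, 95% for bacterial genomes (more permissive because strain
#' variation is high), 99% for all other databases. BLASTn-like databases use
#' an E-value ceiling of 1e-5, MegaBLAST-like ones 1e-9. The rRNA policy sets
#' `host_exclusion_rank = "tribe"`: rRNA is too conserved to distinguish the
#' focal predator from close relatives, so hits sharing a tribe-level (or
#' lower) ancestor with the host are non-diagnostic.
#'
#' @return Named list of [MatchPolicy()] objects, one per marker class.
#' @export
defaultPolicies <- function() {
  list(
    insect_mitogenome = MatchPolicy(98, 225, 1e-5, 3, "blastn_like"),
    cox1_barcode      = MatchPolicy(99, 225, 1e-9, 3, "megablast_like"),
    nuclear_genome    = MatchPolicy(99, 225, 1e-9, 3, "megablast_like"),
    parasitoid_markers = MatchPolicy(99, 225, 1e-5, 3, "blastn_like"),
    rrna              = MatchPolicy(99, 225, 1e-5, 3, "blastn_like",
                                    host_exclusion_rank = "tribe"),
    bacterial_genome  = MatchPolicy(95, 225, 1e-9, 3, "megablast_like")
  )
}

#' Read per-database matching policies from a YAML config
#'
#' Each top-level key is a database id with fields `min_identity`,
#' `min_overlap`, `max_evalue`, `max_targets`, `algorithm_hint` and
#' `host_exclusion_rank`; missing fields fall back to [MatchPolicy()]
#' defaults.
#'
#' @param path YAML file.
#' @return Named list of [MatchPolicy()] objects.
#' @export
policiesFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) {
    MatchPolicy(
      min_identity = x$min_identity %||% 99,
      min_overlap = x$min_overlap %||% 225,
      max_evalue = x$max_evalue %||% 1e-5,
      max_targets = x$max_targets %||% 3,
      algorithm_hint = x$algorithm_hint %||% "blastn_like",
      host_exclusion_rank = x$host_exclusion_rank %||% NA_character_
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a reference database from FASTA plus a taxon metadata table
#'
#' Every FASTA record must have a row in the metadata table mapping its
#' `seq_id` to a `taxon_id`; records without metadata are a hard error that
#' names the offending ids (never silently dropped). Masked regions
#' (mitochondrial control regions, tandem repeats, markers shared with the
#' host) can be supplied as a BED-style table and are validated against
#' sequence bounds.
#'
#' @param fasta_path FASTA file of reference sequences, or a named
#'   `DNAStringSet`.
#' @param metadata data.frame (or TSV path) with columns `seq_id`, `taxon_id`.
#' @param policy a [MatchPolicy()] for this database.
#' @param db_id short database name.
#' @param marker_class one of insect_mitogenome, cox1_barcode, nuclear_genome,
#'   parasitoid_markers, rrna, bacterial_genome.
#' @param masked optional masked-region table (`seq_id`, `start`, `end`,
#'   `reason`; 0-based half-open) or BED path (see [readMaskedBed()]).
#' @return A validated [ReferenceDatabase-class].
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTACGT", s2 = "GGGTTTAAACCC"))
#' md <- data.frame(seq_id = c("s1", "s2"), taxon_id = c("taxA", "taxB"))
#' loadDatabase(seqs, md, MatchPolicy(), db_id = "demo",
#'              marker_class = "insect_mitogenome")
#' @export
loadDatabase <- function(fasta_path, metadata, policy = MatchPolicy(),
                         db_id = "db", marker_class = "insect_mitogenome",
                         masked = NULL) {
  seqs <- if (is(fasta_path, "DNAStringSet")) fasta_path
          else Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: no reference sequences")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- read.delim(metadata, stringsAsFactors = FALSE)
  missing <- setdiff(names(seqs), metadata$seq_id)
  if (length(missing))
    stop("FASTA records without metadata rows: ",
         paste(missing, collapse = ", "))
  taxa <- setNames(as.character(metadata$taxon_id),
                   metadata$seq_id)[names(seqs)]
  if (is.character(masked) && length(masked) == 1L)
    masked <- readMaskedBed(masked)
  if (is.null(masked))
    masked <- data.frame(seq_id = character(), start = integer(),
                         end = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  new("ReferenceDatabase", db_id = db_id, marker_class = marker_class,
      sequences = seqs, seq_taxon = taxa, policy = policy,
      masked = as.data.frame(masked))
}

#' Read masked regions from a BED 3+1 file
#'
#' Columns: seq_id, start, end (0-based half-open, the BED convention) and
#' reason (`control_region`, `ssr` or `shared_marker`).
#'
#' @param path BED file.
#' @return data.frame with columns `seq_id`, `start`, `end`, `reason`.
#' @export
readMaskedBed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("masked-region BED needs 4 columns")
  data.frame(seq_id = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), reason = bed[[4]],
             stringsAsFactors = FALSE)
}

#' Merge overlapping or touching intervals
#'
#' @param regions data.frame with `start`, `end` (0-based half-open) and
#'   optionally `seq_id`/`reason`; merging is per `seq_id`, and the reason of
#'   the first (leftmost) member is kept.
#' @return merged data.frame, sorted by seq_id then start. Idempotent.
#' @export
mergeRegions <- function(regions) {
  if (nrow(regions) == 0L) return(regions)
  if (is.null(regions$seq_id)) regions$seq_id <- "."
  if (is.null(regions$reason)) regions$reason <- "ssr"
  out <- lapply(split(regions, regions$seq_id), function(r) {
    r <- r[order(r$start, r$end), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L, end = r$end))
    hit <- IRanges::findOverlaps(IRanges::IRanges(r$start + 1L, r$end), ir,
                                 select = "first")
    data.frame(seq_id = r$seq_id[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               reason = r$reason[!duplicated(hit)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Detect short-sequence-repeat (SSR) regions in a nucleotide sequence
#'
#' Finds maximal perfect tandem-repeat runs of motif length 1-6 bp whose total
#' run length reaches `min_total_len`, and reports them as merged 0-based
#' half-open intervals with reason `"ssr"`. Such low-complexity regions
#' produce non-diagnostic alignments and are masked from identification.
#' Positions containing N never extend a run.
#'
#' @param sequence character string or `DNAString` over A,C,G,T,N.
#' @param motif_len_range integer vector of motif lengths (default 1:6).
#' @param min_total_len minimum total run length in bp (default 12).
#' @return data.frame (`start`, `end`, `reason`), possibly empty.
#' @examples
#' detectSsrRegions(strrep("AC", 10))           # one run covering [0, 20)
#' detectSsrRegions("ACGTACGGTCA")              # none reach 12 bp
#' @export
detectSsrRegions <- function(sequence, motif_len_range = 1:6,
                             min_total_len = 12) {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  if (L == 0L)
    return(data.frame(start = integer(), end = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  x <- charToRaw(sequence)
  valid <- x != charToRaw("N")
  found <- list()
  for (m in motif_len_range) {
    if (L < m + 1L) next
    eq <- x[seq_len(L - m)] == x[seq.int(m + 1L, L)] &
      valid[seq_len(L - m)] & valid[seq.int(m + 1L, L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values)
    for (i in run) {
      total <- r$lengths[i] + m          # run covers [starts[i], ends[i]+m]
      if (total >= min_total_len && total >= 2L * m)
        found[[length(found) + 1L]] <-
          c(start = starts[i] - 1L, end = ends[i] + m)
    }
  }
  if (length(found) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  df <- as.data.frame(do.call(rbind, found))
  df$reason <- "ssr"
  out <- mergeRegions(df)
  out$seq_id <- NULL
  rownames(out) <- NULL
  out[, c("start", "end", "reason")]
}
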