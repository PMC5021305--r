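# Matching stage: seed-and-extend local alignment of reads against a
# reference database, Karlin-Altschul E-values, BLAST tabular interop.

HIT_COLUMNS <- c("read_id", "db_id", "seq_id", "taxon_id", "percent_identity",
                 "alignment_length", "read_start", "read_end",
                 "subject_start", "subject_end", "strand", "raw_score",
                 "evalue")

#' An empty alignment-hit table
#'
#' Hits are plain data.frames with one row per read/subject pair: identity
#' and alignment length in outfmt-6 semantics (matches / columns including
#' gaps), 0-based half-open read and subject intervals (subject
#' forward-strand normalized, `strand` recording the match orientation),
#' raw alignment score and E-value.
#'
#' @return zero-row data.frame with the canonical hit columns.
#' @export
emptyHits <- function() {
  df <- data.frame(read_id = character(), db_id = character(),
                   seq_id = character(), taxon_id = character(),
                   percent_identity = numeric(), alignment_length = integer(),
                   read_start = integer(), read_end = integer(),
                   subject_start = integer(), subject_end = integer(),
                   strand = character(), raw_score = numeric(),
                   evalue = numeric(), stringsAsFactors = FALSE)
  df
}

#' Default nucleotide scoring scheme
#'
#' Match +1, mismatch -2, gap open 5, gap extension 2 (a gap of length L
#' costs `gap_open + gap_ext * L`) — the classic stringent nucleotide-search
#' defaults.
#'
#' @param match,mismatch,gap_open,gap_ext scoring parameters (penalties
#'   positive).
#' @return named list.
#' @export
alignScoring <- function(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

#' Build an exact k-mer seed index over both strands of a database
#'
#' @param db a [ReferenceDatabase-class] (or named `DNAStringSet`).
#' @param k seed length, in \[8, 16\] (default 12). K-mers containing N are
#'   skipped.
#' @return a `SeedIndex` handle (opaque; see [seedLookup()],
#'   [seedCounts()]).
#' @export
buildSeedIndex <- function(db, k = 12) {
  seqs <- if (is(db, "ReferenceDatabase")) refSequences(db) else db
  ptr <- cpp_build_index(as.character(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), seq_ids = names(seqs),
                 db_len = sum(Biostrings::width(seqs))),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("SeedIndex: k =", info$k, "|", info$n_seqs, "sequences |",
      format(info$n_postings, big.mark = ","), "postings (both strands)\n")
  invisible(x)
}

#' @rdname buildSeedIndex
#' @param index a `SeedIndex`.
#' @param kmer a k-length string; postings (subject, position, strand) where
#'   it occurs exactly.
#' @export
seedLookup <- function(index, kmer) cpp_index_lookup(index$ptr, kmer)

#' @rdname buildSeedIndex
#' @export
seedCounts <- function(index) cpp_index_counts(index$ptr)

#' Solve the Karlin-Altschul lambda for a scoring scheme
#'
#' The scale parameter lambda is the positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` over base pairs, given background
#' base frequencies `p` and the match/mismatch scores. Solved numerically;
#' failure to bracket a root is an error.
#'
#' @param scoring an [alignScoring()] list.
#' @param base_freqs background base frequencies (length 4, sums to 1).
#' @return lambda (numeric scalar).
#' @export
alignmentLambda <- function(scoring = alignScoring(),
                            base_freqs = rep(0.25, 4)) {
  if (abs(sum(base_freqs) - 1) > 1e-6) stop("base_freqs must sum to 1")
  pm <- sum(outer(base_freqs, base_freqs) * diag(4))       # identical pairs
  f <- function(l) pm * exp(l * scoring$match) +
    (1 - pm) * exp(l * scoring$mismatch) - 1
  upper <- 10
  if (f(upper) < 0 || f(1e-4) > 0)
    stop("lambda solve failed: scoring scheme has no positive expected-score root")
  uniroot(f, c(1e-4, upper), tol = 1e-12)$root
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the read length, `n` the
#' database length and lambda solved from the scoring scheme via
#' [alignmentLambda()]. K is treated as a configurable constant.
#'
#' @param raw_score raw alignment score(s), >= 0.
#' @param read_len read (query) length in bp.
#' @param db_len total database length in bp.
#' @param K Karlin-Altschul K constant (default 0.1).
#' @param scoring an [alignScoring()] list.
#' @param lambda optionally, a precomputed lambda.
#' @return numeric E-value(s).
#' @export
estimateEvalue <- function(raw_score, read_len, db_len, K = 0.1,
                           scoring = alignScoring(), lambda = NULL) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0")
  if (is.null(lambda)) lambda <- alignmentLambda(scoring)
  K * as.numeric(read_len) * as.numeric(db_len) * exp(-lambda * raw_score)
}

#' Align reads against a reference database
#'
#' Seed-and-extend local alignment: exact k-mer seeds on both strands are
#' clustered by subject and diagonal, and each cluster is extended by an
#' affine-gap Smith-Waterman restricted to the seed-defined subject window.
#' No query masking is performed (the equivalent of searching with low-
#' complexity filtering disabled); identity thresholds are deliberately NOT
#' applied here — this stage reports every hit passing the E-value ceiling,
#' and threshold filtering belongs to the identification stage.
#'
#' Per read, at most `max_targets` distinct subject sequences are retained
#' (best raw score first; ties broken by higher identity, then lexicographic
#' subject id), keeping only the best local alignment per subject.
#'
#' @param reads a [ShotgunReads][shotgunReads()], named character vector or
#'   `DNAStringSet`.
#' @param db a [ReferenceDatabase-class]; its [MatchPolicy()] supplies the
#'   E-value ceiling and max_targets.
#' @param index optional prebuilt [buildSeedIndex()] for `db`.
#' @param k seed length when building the index here.
#' @param scoring an [alignScoring()] list.
#' @param K Karlin-Altschul constant for [estimateEvalue()].
#' @param min_seed_count minimum seeds per cluster before extension
#'   (default 2; screens out chance single-seed collisions).
#' @param min_seed_span minimum read-position span of a cluster's seeds
#'   before extension (default `k`): overlapping k-mers arising from one
#'   chance shared word are not independent evidence, so a cluster must
#'   cover at least two non-overlapping seeds. Alignments supported by less
#'   than ~2k matching bases are skipped (they could never reach a 225 bp
#'   overlap filter anyway).
#' @param pad subject-window padding around the seed cluster, bp.
#' @param diag_gap maximum diagonal drift joining seeds into one cluster.
#' @return a hit data.frame (see [emptyHits()] for columns).
#' @export
alignReads <- function(reads, db, index = NULL, k = 12,
                       scoring = alignScoring(), K = 0.1,
                       min_seed_count = 2, min_seed_span = NULL,
                       pad = 30, diag_gap = 15) {
  if (is(reads, "ShotgunReads")) {
    ids <- reads@id
    seqs <- reads@sequence
  } else {
    seqs <- as.character(reads)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  }
  if (is.null(index)) index <- buildSeedIndex(db, k = k)
  if (is.null(min_seed_span)) min_seed_span <- index$k
  policy <- matchPolicy(db)
  raw <- cpp_align_reads(index$ptr, unname(seqs),
                         as.integer(min_seed_count),
                         as.integer(min_seed_span), as.integer(pad),
                         as.integer(diag_gap),
                         as.integer(scoring$match), as.integer(scoring$mismatch),
                         as.integer(scoring$gap_open), as.integer(scoring$gap_ext),
                         1L)
  if (nrow(raw) == 0L) return(emptyHits())
  lambda <- alignmentLambda(scoring)
  hits <- data.frame(
    read_id = ids[raw$read],
    db_id = dbId(db),
    seq_id = index$seq_ids[raw$seq],
    taxon_id = unname(seqTaxon(db)[index$seq_ids[raw$seq]]),
    percent_identity = 100 * raw$matches / raw$alignment_length,
    alignment_length = raw$alignment_length,
    read_start = raw$read_start, read_end = raw$read_end,
    subject_start = raw$subject_start, subject_end = raw$subject_end,
    strand = raw$strand, raw_score = as.numeric(raw$raw_score),
    evalue = estimateEvalue(raw$raw_score, nchar(seqs)[raw$read],
                            index$db_len, K = K, lambda = lambda),
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= policy@max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(emptyHits())
  # per-read max_targets cap: best score first, ties by identity then seq_id
  ord <- order(hits$read_id, -hits$raw_score, -hits$percent_identity,
               hits$seq_id)
  hits <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(hits)), hits$read_id, FUN = seq_along)
  hits <- hits[rank <= policy@max_targets, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Import BLAST tabular (outfmt 6) hits
#'
#' Reads the standard 12-column tabular format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) and converts
#' coordinates to the package convention: 0-based half-open intervals,
#' subject interval forward-strand normalized with `sstart > send` encoded as
#' strand `-`. `pident` and `length` pass through unmodified; `bitscore` is
#' used as the raw score. Malformed rows are an error naming the line number.
#'
#' @param path tabular file.
#' @param db_id database label to attach.
#' @param taxon_map optional named vector mapping subject seq_id to taxon_id.
#' @return a hit data.frame (see [emptyHits()]).
#' @export
importBlastTabular <- function(path, db_id, taxon_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(emptyHits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 12L)
      stop("malformed outfmt-6 row at line ", i, ": expected 12 columns, got ",
           length(p))
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(num))
      stop("malformed outfmt-6 row at line ", i, ": non-numeric field")
    qs <- num[5]; qe <- num[6]; ss <- num[7]; se <- num[8]
    minus <- ss > se
    out[[i]] <- data.frame(
      read_id = p[1], db_id = db_id, seq_id = p[2],
      taxon_id = if (!is.null(taxon_map)) unname(taxon_map[p[2]]) else NA_character_,
      percent_identity = num[1], alignment_length = as.integer(num[2]),
      read_start = as.integer(min(qs, qe) - 1), read_end = as.integer(max(qs, qe)),
      subject_start = as.integer(min(ss, se) - 1),
      subject_end = as.integer(max(ss, se)),
      strand = if (minus) "-" else "+",
      raw_score = num[10], evalue = num[9], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

#' Export hits as BLAST tabular (outfmt 6)
#'
#' Inverse of [importBlastTabular()]: intervals go back to 1-based inclusive
#' coordinates with minus-strand hits encoded by `sstart > send`. The
#' `mismatch` and `gapopen` columns are reconstructed approximately
#' (mismatches as non-identical columns; gap opens as 0) since the package
#' does not retain per-column traces.
#'
#' @param hits a hit data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportBlastTabular <- function(hits, path) {
  minus <- hits$strand == "-"
  ss <- ifelse(minus, hits$subject_end, hits$subject_start + 1L)
  se <- ifelse(minus, hits$subject_start + 1L, hits$subject_end)
  mm <- round(hits$alignment_length * (1 - hits$percent_identity / 100))
  df <- data.frame(hits$read_id, hits$seq_id,
                   sprintf("%.3f", hits$percent_identity),
                   hits$alignment_length, mm, 0L,
                   hits$read_start + 1L, hits$read_end, ss, se,
                   format(hits$evalue, digits = 3), hits$raw_score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
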