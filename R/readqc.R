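# Read QC: FASTQ I/O, adapter clipping, quality filtering, FASTA conversion.

#' Read and write FASTQ
#'
#' Thin wrappers around Biostrings FASTQ support, converting to and from the
#' package's in-memory [ShotgunReads][shotgunReads()] representation
#' (Sanger/Phred+33 qualities).
#'
#' @param path FASTQ file.
#' @param reads a `ShotgunReads` object.
#' @return `readFastq()`: a `ShotgunReads`; `writeFastq()`: `path`,
#'   invisibly.
#' @export
readFastq <- function(path) {
  # the FASTQ parser attaches metadata columns that the QualityScaled
  # constructor then (harmlessly) drops with a warning; silence just that
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  new("ShotgunReads",
      id = names(x),
      sequence = unname(as.character(x)),
      quality = unname(as.character(Biostrings::quality(x))))
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads@sequence)
  names(x) <- reads@id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads@quality))
  invisible(path)
}

#' Mean Phred quality per read
#'
#' @param reads a [ShotgunReads][shotgunReads()] object.
#' @return numeric vector (NaN for zero-length reads).
#' @export
meanPhred <- function(reads) {
  cpp_mean_phred(reads@quality)
}

#' Clip 3' adapter contamination
#'
#' For each read, scans left to right for the leftmost position at which the
#' adapter matches the read suffix (the adapter is anchored to run toward the
#' 3' end): at candidate start `i` the aligned length is the smaller of the
#' remaining read length and the adapter length, and a candidate qualifies
#' when at least `min_match` bases are aligned with a mismatch fraction of at
#' most `max_mismatch_rate`. The adapter and everything 3' of it are removed;
#' reads clipped to zero length are dropped. Base calls are never altered.
#'
#' This is a deliberately simple, fully specified clip (one pass, no
#' palindrome mode) standing in for read-trimmer adapter removal.
#'
#' @param reads a [ShotgunReads][shotgunReads()] object.
#' @param adapter_sequences character vector of adapter sequences, or a FASTA
#'   path.
#' @param min_match minimum aligned bases (default 10).
#' @param max_mismatch_rate maximum mismatch fraction among aligned bases
#'   (default 0.2).
#' @return a `ShotgunReads` with clipped reads; zero-length reads removed.
#' @export
trimAdapters <- function(reads, adapter_sequences, min_match = 10,
                         max_mismatch_rate = 0.2) {
  if (length(adapter_sequences) == 1L && file.exists(adapter_sequences))
    adapter_sequences <- as.character(Biostrings::readDNAStringSet(adapter_sequences))
  adapter_sequences <- toupper(adapter_sequences)
  if (length(adapter_sequences) == 0L || any(!nzchar(adapter_sequences)))
    stop("adapters must be non-empty sequences")
  clip <- rep(NA_integer_, length(reads))
  for (ad in adapter_sequences) {
    pos <- cpp_find_adapter(reads@sequence, ad, as.integer(min_match),
                            as.numeric(max_mismatch_rate))
    clip <- pmin(clip, pos, na.rm = TRUE)
  }
  hit <- !is.na(clip)
  seqs <- reads@sequence
  quals <- reads@quality
  seqs[hit] <- substr(seqs[hit], 1L, clip[hit] - 1L)
  quals[hit] <- substr(quals[hit], 1L, clip[hit] - 1L)
  keep <- nchar(seqs) > 0L
  new("ShotgunReads", id = reads@id[keep], sequence = seqs[keep],
      quality = quals[keep])
}

#' Filter reads on Phred quality
#'
#' In the default `"mean"` mode a read is kept iff its arithmetic mean Phred
#' score is at least `min_phred`; kept reads are untouched, so the operation
#' is idempotent. The alternative `"trim3"` mode instead trims low-quality
#' bases from the 3' end (the dominant Illumina failure mode) until the last
#' base reaches `min_phred`, then drops empty reads.
#'
#' @param reads a [ShotgunReads][shotgunReads()] object.
#' @param min_phred quality threshold (default 20).
#' @param mode `"mean"` (read-level filter) or `"trim3"` (per-base 3' trim).
#' @return a filtered `ShotgunReads`.
#' @export
qualityFilter <- function(reads, min_phred = 20, mode = c("mean", "trim3")) {
  mode <- match.arg(mode)
  if (mode == "mean") {
    keep <- meanPhred(reads) >= min_phred
    keep[is.na(keep)] <- FALSE
    return(reads[keep])
  }
  keep_len <- cpp_trim3_length(reads@quality, as.integer(min_phred))
  seqs <- substr(reads@sequence, 1L, keep_len)
  quals <- substr(reads@quality, 1L, keep_len)
  ok <- keep_len > 0L
  new("ShotgunReads", id = reads@id[ok], sequence = seqs[ok],
      quality = quals[ok])
}

#' Convert reads to FASTA records
#'
#' Order- and id-preserving conversion; qualities are discarded. Following
#' FASTA conventions, the record id is the header token before the first
#' whitespace and the full original id is preserved as the header
#' (description) line.
#'
#' @param reads a [ShotgunReads][shotgunReads()] object.
#' @param path optional file; when given, records are written as FASTA.
#' @return a `DNAStringSet` named with the full headers (use [fastaId()] for
#'   the whitespace-truncated ids).
#' @export
toFasta <- function(reads, path = NULL) {
  x <- Biostrings::DNAStringSet(reads@sequence)
  names(x) <- reads@id
  if (!is.null(path)) Biostrings::writeXStringSet(x, path)
  x
}

#' @rdname toFasta
#' @param header FASTA header line(s).
#' @export
fastaId <- function(header) sub("\\s.*$", "", header)
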