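# End-to-end identification pipeline and truth-based evaluation.

#' Identify host and foreign DNA in a gut-content library
#'
#' Runs the complete identification stage over one predator library:
#' quality filtering, alignment against every reference database
#' (E-value ceiling and max-target cap per database policy), overlap and
#' identity threshold filtering, masked-region and host-lineage exclusion,
#' read-level host/foreign separation, score-tolerant LCA taxon assignment
#' and per-database detection tallies.
#'
#' Read bookkeeping is exhaustive: every QC-passing read is counted exactly
#' once, with category priority host > assigned foreign > excluded >
#' unmatched (a read excluded in one database but assigned in another counts
#' as assigned).
#'
#' @param reads a [ShotgunReads][shotgunReads()] library.
#' @param databases named list of [ReferenceDatabase-class] objects.
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param focal_predator taxon id of the host predator.
#' @param predator_id library label (defaults to `focal_predator`).
#' @param min_mean_phred QC threshold ([qualityFilter()]).
#' @param adapters optional adapter sequences for [trimAdapters()].
#' @param score_tolerance LCA grouping tolerance ([assignTaxa()]).
#' @param k seed length for [alignReads()].
#' @param verbose print stage progress.
#' @return list with `detections` (see [tallyDetections()]), `hits`
#'   (surviving foreign hits), `counts` (named read tallies: `total`, `qc`,
#'   `host`, `foreign_assigned`, `excluded`, `unmatched`) and `excluded`
#'   (hit rows removed by masks or host-lineage exclusion, with reasons).
#' @export
identifyGutContents <- function(reads, databases, taxonomy, focal_predator,
                                predator_id = focal_predator,
                                min_mean_phred = 20, adapters = NULL,
                                score_tolerance = 0.98, k = 12,
                                verbose = FALSE) {
  total <- length(reads)
  if (!is.null(adapters)) reads <- trimAdapters(reads, adapters)
  reads <- qualityFilter(reads, min_phred = min_mean_phred)
  qc <- length(reads)
  say <- function(...) if (verbose) message(...)
  say("QC: ", qc, "/", total, " reads pass")
  all_kept <- list()
  all_excl <- list()
  marker_classes <- vapply(databases, markerClass, character(1))
  names(marker_classes) <- vapply(databases, dbId, character(1))
  for (db in databases) {
    say("aligning against ", dbId(db), " (", markerClass(db), ")")
    hits <- alignReads(reads, db, k = k)
    hits <- filterHits(hits, matchPolicy(db))
    masked <- excludeMasked(hits, maskedRegions(db))
    hits <- masked$kept
    excl <- masked$excluded
    her <- matchPolicy(db)@host_exclusion_rank
    if (!is.na(her) && nrow(hits)) {
      hl <- excludeHostLineage(hits, taxonomy, focal_predator, her)
      hits <- hl$kept
      if (nrow(hl$excluded)) {
        hl$excluded$reason <- "host_lineage"
        excl <- rbind(excl, hl$excluded)
      }
    }
    all_kept[[dbId(db)]] <- hits
    all_excl[[dbId(db)]] <- excl
  }
  kept <- do.call(rbind, c(all_kept, list(emptyHits())))
  excluded <- do.call(rbind, all_excl)
  rownames(kept) <- NULL
  sep <- separateHost(kept, taxonomy, focal_predator)
  assignments <- assignTaxa(sep$foreign, taxonomy,
                            score_tolerance = score_tolerance)
  detections <- tallyDetections(assignments, predator_id,
                                marker_classes = marker_classes)
  host_reads <- unique(sep$host$read_id)
  assigned_reads <- unique(assignments$read_id)
  excl_reads <- setdiff(unique(excluded$read_id),
                        c(host_reads, assigned_reads))
  counts <- c(total = total, qc = qc,
              host = length(host_reads),
              foreign_assigned = length(assigned_reads),
              excluded = length(excl_reads),
              unmatched = qc - length(host_reads) - length(assigned_reads) -
                length(excl_reads))
  list(detections = detections, hits = sep$foreign, counts = counts,
       excluded = excluded)
}

#' Evaluate detections against simulation ground truth
#'
#' Species/genus-level precision and recall of foreign-taxon recovery.
#' Truth-positive taxa are the foreign community members; the recall
#' denominator keeps only taxa with at least `min_reads` reads passing the
#' length and quality gates (template at least `min_overlap` bp and mean
#' Phred at least `min_mean_phred`) — taxa below that have too little
#' surviving signal for detection to be expected.
#'
#' @param detections detection table from [identifyGutContents()].
#' @param truth truth table from [simulateGutReads()].
#' @param reads the simulated [ShotgunReads][shotgunReads()] (for quality
#'   gates).
#' @param min_overlap minimum template length for a read to count as
#'   detectable (match the database policy, default 225).
#' @param min_mean_phred quality gate (default 20).
#' @param min_reads detection support expected per taxon (default 5).
#' @return list: `precision`, `recall`, `detected`, `expected`,
#'   `false_positives`, `false_negatives`. `precision` is NA when nothing
#'   was detected and `recall` is NA when no taxon reaches the support
#'   floor (the criterion is then vacuous at this sequencing depth).
#' @export
evaluateDetections <- function(detections, truth, reads, min_overlap = 225,
                               min_mean_phred = 20, min_reads = 5) {
  detected <- unique(detections$taxon_id[detections$rank %in%
                                           c("species", "genus")])
  foreign <- truth[!truth$is_host, , drop = FALSE]
  all_foreign_taxa <- unique(foreign$taxon_id)
  mq <- meanPhred(reads)
  names(mq) <- reads@id
  pass <- foreign[(foreign$end - foreign$start) >= min_overlap &
                    mq[foreign$read_id] >= min_mean_phred, , drop = FALSE]
  tab <- table(pass$taxon_id)
  expected <- names(tab)[tab >= min_reads]
  fp <- setdiff(detected, all_foreign_taxa)
  fn <- setdiff(expected, detected)
  list(precision = if (length(detected))
         1 - length(fp) / length(detected) else NA_real_,
       recall = if (length(expected))
         1 - length(fn) / length(expected) else NA_real_,
       detected = detected, expected = expected,
       false_positives = fp, false_negatives = fn)
}
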