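# Identification stage: overlap/identity thresholds, masked-region and
# host-lineage exclusion, host/foreign separation, LCA taxon assignment,
# per-database detection tallies.

#' Apply overlap and identity thresholds to hits from one database
#'
#' Keeps exactly the hits with `alignment_length >= min_overlap` and
#' `percent_identity >= min_identity` (both bounds inclusive), preserving
#' input order. This is the core false-positive control of the pipeline:
#' stringent overlap and identity jointly suppress spurious cross-taxon
#' matches from conserved or low-complexity regions.
#'
#' @param hits hit data.frame from a single database (see [emptyHits()]).
#' @param policy that database's [MatchPolicy()].
#' @return the surviving hits.
#' @export
filterHits <- function(hits, policy) {
  keep <- hits$alignment_length >= policy@min_overlap &
    hits$percent_identity >= policy@min_identity
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identity-threshold sensitivity sweep
#'
#' Re-applies [filterHits()] at a series of identity thresholds (overlap held
#' fixed) and reports surviving read and taxon counts. Lowering identity can
#' only add reads and taxa; the sweep quantifies how many of the extra,
#' low-identity matches a stringent threshold removes.
#'
#' @param hits hit data.frame from a single database.
#' @param policy the database [MatchPolicy()] (supplies `min_overlap`).
#' @param identities identity thresholds to evaluate.
#' @param taxonomy optional [Taxonomy][readTaxonomy()]; when given, taxa are
#'   counted after LCA assignment, otherwise as distinct best-hit taxon ids.
#' @param score_tolerance LCA grouping tolerance (see [assignTaxa()]).
#' @return data.frame with `min_identity`, `n_reads`, `n_taxa`.
#' @export
thresholdSweep <- function(hits, policy, identities = c(90, 95, 98, 99),
                           taxonomy = NULL, score_tolerance = 0.98) {
  out <- lapply(identities, function(idt) {
    p <- policy
    p@min_identity <- idt
    surv <- filterHits(hits, p)
    if (nrow(surv) == 0L)
      return(data.frame(min_identity = idt, n_reads = 0L, n_taxa = 0L))
    if (!is.null(taxonomy)) {
      asg <- assignTaxa(surv, taxonomy, score_tolerance = score_tolerance)
      n_taxa <- length(unique(asg$taxon_id[!is.na(asg$taxon_id)]))
    } else {
      best <- surv[order(surv$read_id, -surv$raw_score), , drop = FALSE]
      best <- best[!duplicated(best$read_id), , drop = FALSE]
      n_taxa <- length(unique(best$taxon_id))
    }
    data.frame(min_identity = idt,
               n_reads = length(unique(surv$read_id)), n_taxa = n_taxa)
  })
  do.call(rbind, out)
}

#' Discard hits overlapping masked subject regions
#'
#' A hit is discarded iff its subject interval overlaps a masked interval of
#' its subject sequence by at least `min_mask_overlap` bp (default 1, the
#' conservative reading: any contact with a mitochondrial control region,
#' tandem repeat or host-shared marker disqualifies the read).
#'
#' @param hits hit data.frame.
#' @param masked_regions masked-region table (`seq_id`, `start`, `end`,
#'   `reason`; 0-based half-open), e.g. [maskedRegions()] of the database.
#' @param min_mask_overlap minimum overlap (bp) with a mask to discard.
#' @return list with `kept` (hits) and `excluded` (hits plus a `reason`
#'   column naming the mask type).
#' @export
excludeMasked <- function(hits, masked_regions, min_mask_overlap = 1) {
  if (nrow(hits) == 0L || is.null(masked_regions) ||
      nrow(masked_regions) == 0L) {
    excl <- cbind(hits[0, , drop = FALSE],
                  data.frame(reason = character(), stringsAsFactors = FALSE))
    return(list(kept = hits, excluded = excl))
  }
  reason <- rep(NA_character_, nrow(hits))
  for (sid in unique(masked_regions$seq_id)) {
    m <- masked_regions[masked_regions$seq_id == sid, , drop = FALSE]
    idx <- which(hits$seq_id == sid)
    if (length(idx) == 0L) next
    hr <- IRanges::IRanges(start = hits$subject_start[idx] + 1L,
                           end = hits$subject_end[idx])
    mr <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    ov <- IRanges::findOverlaps(hr, mr, minoverlap = min_mask_overlap)
    if (length(ov)) {
      first <- !duplicated(S4Vectors::queryHits(ov))
      reason[idx[S4Vectors::queryHits(ov)[first]]] <-
        m$reason[S4Vectors::subjectHits(ov)[first]]
    }
  }
  hit_masked <- !is.na(reason)
  excluded <- hits[hit_masked, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[hit_masked]
  else excluded$reason <- character()
  kept <- hits[!hit_masked, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Exclude hits that cannot distinguish prey from the focal predator
#'
#' For markers too conserved to be diagnostic near the host (typically rRNA),
#' any hit whose subject taxon shares an ancestor with the focal predator at
#' or below `host_exclusion_rank` is moved to the excluded set: within that
#' clade the marker does not differentiate prey from predator.
#'
#' @param hits hit data.frame.
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param focal_predator taxon id of the focal predator.
#' @param host_exclusion_rank rank label (e.g. `"tribe"`); unknown labels are
#'   an error.
#' @return list with `excluded` and `kept` hit data.frames.
#' @export
excludeHostLineage <- function(hits, taxonomy, focal_predator,
                               host_exclusion_rank) {
  if (is.na(rankLevel(host_exclusion_rank)))
    stop("unknown rank label: ", host_exclusion_rank)
  if (nrow(hits) == 0L) return(list(excluded = hits, kept = hits))
  taxa <- unique(hits$taxon_id)
  shared <- vapply(taxa, function(t)
    sharesAncestorAtOrBelow(taxonomy, t, focal_predator, host_exclusion_rank),
    logical(1))
  drop <- hits$taxon_id %in% taxa[shared]
  list(excluded = hits[drop, , drop = FALSE],
       kept = hits[!drop, , drop = FALSE])
}

#' Separate host-derived from foreign hits
#'
#' Hits whose subject taxon is the focal predator (or a descendant of it) are
#' host evidence. The partition is read-level, exhaustive and disjoint: a
#' read with both host and foreign hits is resolved to the side with the
#' better raw score, ties going to host (the conservative choice — a read
#' that matches the host as well as any prey is not prey evidence). Foreign
#' output retains only the non-host hits of foreign-resolved reads.
#'
#' @param hits hit data.frame (may span databases).
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param focal_predator taxon id.
#' @return list with `host` and `foreign` hit data.frames.
#' @export
separateHost <- function(hits, taxonomy, focal_predator) {
  if (nrow(hits) == 0L) return(list(host = hits, foreign = hits))
  taxa <- unique(hits$taxon_id)
  is_host_taxon <- setNames(isDescendant(taxonomy, taxa, focal_predator), taxa)
  host_hit <- unname(is_host_taxon[hits$taxon_id])
  reads <- unique(hits$read_id)
  host_best <- tapply(ifelse(host_hit, hits$raw_score, -Inf), hits$read_id, max)
  foreign_best <- tapply(ifelse(host_hit, -Inf, hits$raw_score), hits$read_id, max)
  read_is_host <- host_best[reads] >= foreign_best[reads]   # tie -> host
  read_is_host <- read_is_host & is.finite(host_best[reads])
  host_reads <- reads[read_is_host]
  in_host <- hits$read_id %in% host_reads
  foreign <- hits[!in_host & !host_hit, , drop = FALSE]
  host <- hits[in_host, , drop = FALSE]
  rownames(host) <- rownames(foreign) <- NULL
  list(host = host, foreign = foreign)
}

#' Assign reads to the lowest reliably identifiable taxon
#'
#' For each read (within one database), hits whose raw score is within
#' `score_tolerance` of the best (`raw_score >= score_tolerance * best`) are
#' treated as equally credible, and the read is assigned the lowest common
#' ancestor of their taxa. A single unambiguous best hit yields its own
#' taxon; equally good hits to different species in one clade yield that
#' clade — the automated version of reporting "the taxonomic level at which
#' the match is reliable" when a conserved region is identical across
#' relatives.
#'
#' `assignTaxon()` operates on the hits of one read; `assignTaxa()` maps it
#' over a hit table grouped by `(read_id, db_id)`.
#'
#' @param hits hit data.frame (for `assignTaxon()`: hits of a single read in
#'   a single database; >= 1 row).
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param score_tolerance fraction of the best score still considered tied
#'   (default 0.98).
#' @return `assignTaxon()`: list with `taxon_id` and `rank`;
#'   `assignTaxa()`: data.frame `read_id`, `db_id`, `taxon_id`, `rank`.
#' @export
assignTaxon <- function(hits, taxonomy, score_tolerance = 0.98) {
  stopifnot(nrow(hits) >= 1L)
  best <- max(hits$raw_score)
  sel <- hits$raw_score >= score_tolerance * best
  lcaTaxon(taxonomy, hits$taxon_id[sel])
}

#' @rdname assignTaxon
#' @export
assignTaxa <- function(hits, taxonomy, score_tolerance = 0.98) {
  if (nrow(hits) == 0L)
    return(data.frame(read_id = character(), db_id = character(),
                      taxon_id = character(), rank = character(),
                      stringsAsFactors = FALSE))
  key <- paste(hits$read_id, hits$db_id, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  out <- lapply(groups, function(idx) {
    a <- assignTaxon(hits[idx, , drop = FALSE], taxonomy, score_tolerance)
    data.frame(read_id = hits$read_id[idx[1]], db_id = hits$db_id[idx[1]],
               taxon_id = a$taxon_id, rank = a$rank, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tally per-database taxon detections
#'
#' Groups read assignments by `(db_id, taxon)` and counts reads; output is
#' sorted by database then descending read count. Assignments must already be
#' unique per `(read_id, db_id)` — each read contributes at most one count
#' per database.
#'
#' @param assignments data.frame from [assignTaxa()].
#' @param predator_id label of the focal predator library.
#' @param marker_classes optional named vector mapping db_id to marker class,
#'   carried through for downstream network building.
#' @return data.frame `predator_id`, `db_id`, `marker_class`, `taxon_id`,
#'   `rank`, `read_count`, `read_ids` (semicolon-joined).
#' @export
tallyDetections <- function(assignments, predator_id, marker_classes = NULL) {
  assignments <- assignments[!is.na(assignments$taxon_id), , drop = FALSE]
  if (nrow(assignments) == 0L)
    return(data.frame(predator_id = character(), db_id = character(),
                      marker_class = character(), taxon_id = character(),
                      rank = character(), read_count = integer(),
                      read_ids = character(), stringsAsFactors = FALSE))
  if (anyDuplicated(paste(assignments$read_id, assignments$db_id)))
    stop("assignments must be unique per (read_id, db_id)")
  key <- paste(assignments$db_id, assignments$taxon_id, sep = "\r")
  groups <- split(seq_len(nrow(assignments)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(predator_id = predator_id,
               db_id = assignments$db_id[idx[1]],
               marker_class = if (!is.null(marker_classes))
                 unname(marker_classes[assignments$db_id[idx[1]]]) else NA_character_,
               taxon_id = assignments$taxon_id[idx[1]],
               rank = assignments$rank[idx[1]],
               read_count = length(idx),
               read_ids = paste(sort(assignments$read_id[idx]), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$db_id, -out$read_count, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
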