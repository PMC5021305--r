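# Threshold filtering, masked/host exclusions, host separation, LCA
# assignment, detection tallies.

test_that("filterHits applies inclusive overlap and identity bounds", {
  pol98 <- MatchPolicy(98, 225)
  pol95 <- MatchPolicy(95, 225)
  hits <- random_hits(4)
  hits$percent_identity <- c(97.9, 98.0, 99.5, 98.2)
  hits$alignment_length <- c(250L, 225L, 224L, 230L)
  out <- filterHits(hits, pol98)
  # 97.9% discarded at a 98% threshold; 225 bp kept (inclusive); 224 dropped
  expect_identical(out$read_id, hits$read_id[c(2, 4)])
  hits2 <- hits
  hits2$percent_identity <- 95.0
  hits2$alignment_length <- 225L
  expect_equal(nrow(filterHits(hits2, pol95)), 4L)
})

test_that("filterHits equals a brute-force two-predicate scan", {
  set.seed(301)
  hits <- random_hits(1000)
  pol <- MatchPolicy(98, 225)
  got <- filterHits(hits, pol)
  want <- hits[hits$alignment_length >= 225 &
                 hits$percent_identity >= 98, , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("raising thresholds never increases surviving reads or taxa", {
  set.seed(302)
  hits <- random_hits(800)
  prev_reads <- Inf; prev_taxa <- Inf
  for (idt in c(90, 95, 98, 99)) {
    surv <- filterHits(hits, MatchPolicy(idt, 225))
    n_reads <- length(unique(surv$read_id))
    n_taxa <- length(unique(surv$taxon_id))
    expect_lte(n_reads, prev_reads)
    expect_lte(n_taxa, prev_taxa)
    prev_reads <- n_reads; prev_taxa <- n_taxa
  }
  prev <- Inf
  for (ov in c(150, 200, 225, 250, 275)) {
    n <- length(unique(filterHits(hits, MatchPolicy(90, ov))$read_id))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("hits overlapping masked regions are discarded with reasons", {
  hits <- random_hits(2)
  hits$seq_id <- c("s1", "s2")
  hits$subject_start <- c(380L, 100L)
  hits$subject_end <- c(600L, 300L)
  masks <- data.frame(seq_id = "s1", start = 500L, end = 1500L,
                      reason = "control_region", stringsAsFactors = FALSE)
  out <- excludeMasked(hits, masks)
  expect_equal(nrow(out$excluded), 1L)
  expect_identical(out$excluded$seq_id, "s1")
  expect_identical(out$excluded$reason, "control_region")
  expect_identical(out$kept$seq_id, "s2")
  # touching but not overlapping (half-open) is kept
  hits$subject_end[1] <- 500L
  out2 <- excludeMasked(hits, masks)
  expect_equal(nrow(out2$excluded), 0L)
})

test_that("masked exclusion equals a brute-force interval check", {
  set.seed(303)
  hits <- random_hits(500)
  masks <- data.frame(
    seq_id = sample(paste0("s", 1:4), 30, replace = TRUE),
    start = sample.int(1900, 30, replace = TRUE),
    reason = sample(c("control_region", "ssr"), 30, replace = TRUE),
    stringsAsFactors = FALSE)
  masks$end <- masks$start + sample(20:200, 30, replace = TRUE)
  got <- excludeMasked(hits, masks)
  # O(n*m) oracle: any >= 1 bp overlap on the same sequence
  drop <- logical(nrow(hits))
  for (i in seq_len(nrow(hits)))
    for (j in seq_len(nrow(masks)))
      if (hits$seq_id[i] == masks$seq_id[j] &&
          hits$subject_start[i] < masks$end[j] &&
          masks$start[j] < hits$subject_end[i]) drop[i] <- TRUE
  expect_identical(got$excluded$read_id, hits$read_id[drop])
  expect_identical(got$kept$read_id, hits$read_id[!drop])
})

test_that("host-lineage exclusion removes taxa sharing a low-rank ancestor", {
  ex <- exampleGutStudy()
  hits <- random_hits(3, db_id = "rrna")
  hits$taxon_id <- c("Coccinella_septempunctata", "Ascomycota",
                     "Plutella_xylostella")
  # a Coccinellini relative of the focal ladybird is non-diagnostic rRNA
  out <- excludeHostLineage(hits, ex$taxonomy, "Harmonia_axyridis", "tribe")
  expect_identical(out$excluded$taxon_id, "Coccinella_septempunctata")
  expect_setequal(out$kept$taxon_id, c("Ascomycota", "Plutella_xylostella"))
  # a rank below the pair's common ancestor excludes nothing
  out2 <- excludeHostLineage(hits, ex$taxonomy, "Harmonia_axyridis", "genus")
  expect_equal(nrow(out2$excluded), 0L)
  expect_error(
    excludeHostLineage(hits, ex$taxonomy, "Harmonia_axyridis", "cohort"),
    "rank")
})

test_that("separateHost partitions reads with host-favoring ties", {
  ex <- exampleGutStudy()
  h <- random_hits(4)
  h$read_id <- c("r1", "r2", "r3", "r3")
  h$taxon_id <- c("Harmonia_axyridis",      # host-only read
                  "Plutella_xylostella",    # foreign-only read
                  "Harmonia_axyridis", "Plutella_xylostella")  # tied read
  h$raw_score <- c(200, 200, 180, 180)
  out <- separateHost(h, ex$taxonomy, "Harmonia_axyridis")
  expect_setequal(unique(out$host$read_id), c("r1", "r3"))
  expect_identical(unique(out$foreign$read_id), "r2")
  # a better foreign score wins the read
  h$raw_score[4] <- 195
  out2 <- separateHost(h, ex$taxonomy, "Harmonia_axyridis")
  expect_setequal(unique(out2$foreign$read_id), c("r2", "r3"))
  # the foreign partition drops the read's losing host-side hits
  expect_false("Harmonia_axyridis" %in% out2$foreign$taxon_id)
})

test_that("assignTaxon applies the score-tolerant LCA rule", {
  tax <- mini_taxonomy()
  one <- random_hits(2)
  one$taxon_id <- c("Aphis_gossypii", "Encarsia_formosa")
  one$raw_score <- c(240, 180)   # runner-up far outside 0.98 tolerance
  expect_identical(assignTaxon(one, tax),
                   list(taxon_id = "Aphis_gossypii", rank = "species"))
  # equal best hits to two congeneric chalcid species resolve at the genus;
  # adding a same-superfamily third within tolerance lifts it further
  two <- random_hits(2)
  two$taxon_id <- c("Encarsia_formosa", "Encarsia_sophia")
  two$raw_score <- c(230, 230)
  expect_identical(assignTaxon(two, tax),
                   list(taxon_id = "Encarsia", rank = "genus"))
  # duplicate hits to one taxon stay at that taxon
  dup <- random_hits(2)
  dup$taxon_id <- c("Aphis_gossypii", "Aphis_gossypii")
  dup$raw_score <- c(230, 230)
  expect_identical(assignTaxon(dup, tax)$taxon_id, "Aphis_gossypii")
  # hits just inside the tolerance participate in the LCA
  close <- random_hits(2)
  close$taxon_id <- c("Encarsia_formosa", "Encarsia_sophia")
  close$raw_score <- c(250, 246)   # 246 >= 0.98 * 250
  expect_identical(assignTaxon(close, tax)$taxon_id, "Encarsia")
})

test_that("tallyDetections groups, counts and orders detections", {
  asg <- data.frame(
    read_id = paste0("r", 1:13),
    db_id = c(rep("mito", 10), rep("cox1", 3)),
    taxon_id = c(rep("A", 7), rep("B", 3), rep("C", 3)),
    rank = "species", stringsAsFactors = FALSE)
  det <- tallyDetections(asg, "PredatorZ",
                         marker_classes = c(mito = "insect_mitogenome",
                                            cox1 = "cox1_barcode"))
  expect_equal(det$read_count, c(3L, 7L, 3L))    # cox1 first, then by count
  expect_identical(det$taxon_id, c("C", "A", "B"))
  expect_identical(det$marker_class[1], "cox1_barcode")
  expect_equal(nrow(tallyDetections(asg[0, ], "PredatorZ")), 0L)
  dup <- rbind(asg, asg[1, ])
  expect_error(tallyDetections(dup, "PredatorZ"), "unique")
})
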