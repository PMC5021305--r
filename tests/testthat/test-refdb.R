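# Reference-database loading, policies, masked regions, SSR detection.

test_that("loadDatabase validates FASTA records against metadata", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTACGTACGT",
                                     s2 = "GGGTTTAAACCCGGTA",
                                     s3 = "TTTTACGTACGTAAAA"))
  md <- data.frame(seq_id = c("s1", "s2", "s3"),
                   taxon_id = c("taxA", "taxB", "taxB"))
  db <- loadDatabase(seqs, md, MatchPolicy(), db_id = "demo",
                     marker_class = "insect_mitogenome")
  expect_s4_class(db, "ReferenceDatabase")
  expect_length(refSequences(db), 3)
  expect_identical(unname(seqTaxon(db)["s3"]), "taxB")

  # a record with no metadata row is a hard error naming the id
  md2 <- md[md$seq_id != "s2", ]
  names(seqs)[2] <- "seqX"
  expect_error(loadDatabase(seqs, md2, MatchPolicy(), db_id = "demo"),
               "seqX")
  expect_error(
    loadDatabase(Biostrings::DNAStringSet(), md, MatchPolicy()),
    "empty FASTA")
})

test_that("per-database policies load from a YAML config", {
  cfg <- system.file("extdata", "example_policies.yaml", package = "gutlink")
  pol <- policiesFromConfig(cfg)
  expect_equal(pol$mito@min_identity, 98)
  expect_equal(pol$mito@min_overlap, 225)
  expect_equal(pol$bacterial@min_identity, 95)
  expect_equal(pol$cox1@max_evalue, 1e-9)
  expect_identical(pol$rrna@host_exclusion_rank, "tribe")
  expect_equal(pol$parasitoid@max_targets, 3L)
})

test_that("MatchPolicy enforces its invariants", {
  expect_error(MatchPolicy(min_identity = 0), "min_identity")
  expect_error(MatchPolicy(min_identity = 101), "min_identity")
  expect_error(MatchPolicy(min_overlap = 0), "min_overlap")
  expect_error(MatchPolicy(max_targets = 0), "max_targets")
})

test_that("detectSsrRegions finds tandem repeats as half-open intervals", {
  # dinucleotide repeat covering the whole sequence
  expect_equal(detectSsrRegions(strrep("AC", 10))[, c("start", "end")],
               data.frame(start = 0L, end = 20L))
  # nothing reaches the 12 bp threshold
  expect_equal(nrow(detectSsrRegions("ACGTACGGTCA")), 0L)
  # homopolymer run, trailing non-repeat bases excluded
  hom <- detectSsrRegions(paste0(strrep("A", 12), "GG"))
  expect_equal(hom[, c("start", "end")], data.frame(start = 0L, end = 12L))
  # empty input
  expect_equal(nrow(detectSsrRegions("")), 0L)
  # N never extends a run
  expect_equal(nrow(detectSsrRegions(paste0("AAAAA", "N", "AAAAAA"))), 0L)
})

test_that("detectSsrRegions agrees with a brute-force scan on random sequences", {
  set.seed(402)
  for (rep in 1:5) {
    s <- random_dna(1000)
    # plant repeats of several motif lengths
    substr(s, 101, 120) <- strrep("AT", 10)
    substr(s, 301, 318) <- strrep("CAG", 6)
    substr(s, 601, 614) <- strrep("A", 14)
    substr(s, 801, 824) <- strrep("ACGT", 6)
    got <- detectSsrRegions(s)
    expect_identical(regions_to_coverage(got, 1000), ssr_oracle(s),
                     info = paste("replicate", rep))
  }
})

test_that("region merging is idempotent and respects bounds", {
  r <- data.frame(seq_id = "s1", start = c(10, 15, 40), end = c(20, 30, 50),
                  reason = "ssr", stringsAsFactors = FALSE)
  m1 <- mergeRegions(r)
  expect_equal(m1$start, c(10, 40))
  expect_equal(m1$end, c(30, 50))
  expect_identical(mergeRegions(m1), m1)
})

test_that("masked regions outside sequence bounds are rejected", {
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 25)))
  md <- data.frame(seq_id = "s1", taxon_id = "taxA")
  bad <- data.frame(seq_id = "s1", start = 50L, end = 200L,
                    reason = "control_region")
  expect_error(loadDatabase(seqs, md, MatchPolicy(), masked = bad),
               "bounds|length")
  ok <- data.frame(seq_id = "s1", start = 50L, end = 100L,
                   reason = "control_region")
  db <- loadDatabase(seqs, md, MatchPolicy(), masked = ok)
  expect_equal(nrow(maskedRegions(db)), 1L)
})

test_that("validateTaxonomy reports exactly the registry inconsistencies", {
  ex <- exampleGutStudy()
  expect_equal(nrow(validateTaxonomy(list(), ex$taxonomy)), 0L)

  # a species nested under a species is a rank inversion
  bad <- taxonomyTable(ex$taxonomy)
  bad <- rbind(bad, data.frame(taxon_id = "Aphis_gossypii_sub",
                               rank = "species", parent_id = "Aphis_gossypii",
                               guild = "herbivore", tags = ""))
  rep1 <- validateTaxonomy(list(), readTaxonomy(table = bad))
  expect_true(any(rep1$type == "rank_inconsistency" &
                    grepl("Aphis_gossypii_sub", rep1$detail)))

  # an aphid-symbiont tag on a Lepidoptera taxon is flagged
  bad2 <- taxonomyTable(ex$taxonomy)
  bad2$tags[bad2$taxon_id == "Plutella_xylostella"] <- "aphid_specific_symbiont"
  rep2 <- validateTaxonomy(list(), readTaxonomy(table = bad2))
  expect_true(any(rep2$type == "tag_clade_mismatch" &
                    grepl("Plutella_xylostella", rep2$detail)))

  # an unknown tag is flagged
  bad3 <- taxonomyTable(ex$taxonomy)
  bad3$tags[bad3$taxon_id == "Hamiltonella"] <- "mystery_tag"
  rep3 <- validateTaxonomy(list(), readTaxonomy(table = bad3))
  expect_true(any(rep3$type == "unknown_tag"))

  # database taxa missing from the taxonomy are reported per database
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 10)))
  db <- loadDatabase(seqs, data.frame(seq_id = "s1", taxon_id = "NotATaxon"),
                     MatchPolicy(), db_id = "demo")
  rep4 <- validateTaxonomy(list(db), ex$taxonomy)
  expect_true(any(rep4$type == "unresolvable_taxon" &
                    grepl("NotATaxon", rep4$detail)))
})
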