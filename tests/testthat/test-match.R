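# Seed index, seed-and-extend alignment, E-values, BLAST tabular interop.

make_db <- function(seqs, policy = MatchPolicy(98, 225, 1e-5, 3),
                    db_id = "mito") {
  loadDatabase(Biostrings::DNAStringSet(seqs),
               data.frame(seq_id = names(seqs),
                          taxon_id = paste0("tax_", names(seqs))),
               policy, db_id = db_id, marker_class = "insect_mitogenome")
}

test_that("seed index covers both strands with the expected positions", {
  ix <- buildSeedIndex(Biostrings::DNAStringSet(c(s1 = "ACGTACGTACGTACGTACGT")),
                       k = 12)
  counts <- seedCounts(ix)
  expect_equal(counts$count[counts$seq_id == "s1" & counts$strand == "+"],
               9)  # 20 - 12 + 1
  expect_equal(counts$count[counts$seq_id == "s1" & counts$strand == "-"],
               9)
  # a sequence of Ns contributes no seeds
  ixN <- buildSeedIndex(Biostrings::DNAStringSet(c(sN = strrep("N", 40))),
                        k = 12)
  expect_equal(sum(seedCounts(ixN)$count), 0)
  expect_error(buildSeedIndex(Biostrings::DNAStringSet(c(a = "ACGT")), k = 7),
               "k")
})

test_that("seed lookup matches a brute-force position scan", {
  set.seed(21)
  s <- random_dna(500)
  ix <- buildSeedIndex(Biostrings::DNAStringSet(c(chr = s)), k = 12)
  for (probe in c(1, 100, 489)) {
    kmer <- substr(s, probe, probe + 11)
    hits <- seedLookup(ix, kmer)
    fwd <- hits[hits$strand == "+", , drop = FALSE]
    # oracle: scan every window of the subject for the k-mer
    windows <- substring(s, 1:(500 - 11), 12:500)
    expect_setequal(fwd$pos, which(windows == kmer) - 1L)
  }
})

test_that("a verbatim read aligns full-length at identity 100", {
  set.seed(8)
  subj <- random_dna(5000)
  db <- make_db(c(s1 = subj))
  read <- substr(subj, 1001, 1250)
  h <- alignReads(shotgunReads("r1", read), db)
  expect_equal(nrow(h), 1L)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$alignment_length, 250L)
  expect_equal(h$raw_score, 250)
  expect_equal(h$subject_start, 1000L)
  expect_equal(h$subject_end, 1250L)
  expect_equal(h$read_start, 0L)
  expect_equal(h$read_end, 250L)
  expect_identical(h$taxon_id, "tax_s1")
})

test_that("five substitutions give identity 98.0 and score 235", {
  set.seed(9)
  subj <- random_dna(5000)
  db <- make_db(c(s1 = subj))
  read <- mutate_seq(substr(subj, 2001, 2250), c(20, 70, 120, 170, 220))
  h <- alignReads(shotgunReads("r1", read), db)
  expect_equal(h$percent_identity, 98)
  expect_equal(h$raw_score, 250 - 5 * 3)   # +1 match, -2 mismatch
  expect_equal(h$alignment_length, 250L)
})

test_that("matching reports sub-threshold-identity hits (stage separation)", {
  set.seed(10)
  subj <- random_dna(5000)
  db <- make_db(c(s1 = subj))   # downstream policy wants 98%
  read <- mutate_seq(substr(subj, 101, 350), sample(250, 25))  # ~10% div
  h <- alignReads(shotgunReads("r1", read), db)
  expect_equal(nrow(h), 1L)
  expect_lt(h$percent_identity, 95)
  expect_gt(h$percent_identity, 85)
})

test_that("strand symmetry: a read and its reverse complement score alike", {
  set.seed(11)
  subj <- random_dna(4000)
  db <- make_db(c(s1 = subj))
  for (i in 1:5) {
    start <- sample(1:3700, 1)
    read <- mutate_seq(substr(subj, start, start + 249),
                       sample(250, 5))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    hf <- alignReads(shotgunReads("f", read), db)
    hr <- alignReads(shotgunReads("r", rc), db)
    expect_equal(hr$raw_score, hf$raw_score)
    expect_equal(hr$percent_identity, hf$percent_identity)
    expect_equal(hr$subject_start, hf$subject_start)
    expect_equal(hr$subject_end, hf$subject_end)
    expect_identical(sort(c(hf$strand, hr$strand)), c("+", "-"))
  }
})

test_that("max_targets caps distinct subjects, best score first", {
  set.seed(12)
  base <- random_dna(2000)
  variants <- c(s1 = base,
                s2 = mutate_seq(base, sample(2000, 20)),
                s3 = mutate_seq(base, sample(2000, 40)),
                s4 = mutate_seq(base, sample(2000, 60)),
                s5 = mutate_seq(base, sample(2000, 80)))
  db <- make_db(variants, policy = MatchPolicy(98, 225, 1e-5, 3))
  read <- substr(base, 501, 750)
  h <- alignReads(shotgunReads("r1", read), db)
  expect_lte(nrow(h), 3L)
  expect_identical(h$seq_id[1], "s1")           # exact copy scores best
  expect_true(all(diff(h$raw_score) <= 0))      # descending
})

test_that("Karlin-Altschul E-values follow the closed form", {
  lambda <- alignmentLambda()
  # bisection oracle for the positive root of 0.25 e^l + 0.75 e^-2l = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 0.1; hi <- 5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_lt(abs(lambda - (lo + hi) / 2), 1e-6)
  # S = 0 reduces to K * m * n
  expect_equal(estimateEvalue(0, 250, 1e6, K = 0.1), 0.1 * 250 * 1e6)
  # linear in database length
  expect_equal(estimateEvalue(50, 250, 2e6),
               2 * estimateEvalue(50, 250, 1e6))
  expect_error(estimateEvalue(-1, 250, 1e6), "raw_score")
  # a scheme with positive expected score has no finite lambda
  expect_error(alignmentLambda(alignScoring(match = 2, mismatch = -0.1)),
               "lambda")
})

test_that("BLAST tabular import converts coordinates and passes fields through", {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "read1\tsubj1\t98.222\t250\t4\t0\t1\t250\t100\t349\t1e-60\t231",
    "read2\tsubj1\t95.000\t240\t12\t0\t3\t242\t100\t1\t1e-40\t180",
    paste(paste0("r", 3:12), "subjX", "99.1", "230", "2", "0", "1", "230",
          "501", "730", "1e-50", "210", sep = "\t"))
  writeLines(rows, path)
  hits <- importBlastTabular(path, db_id = "mito")
  expect_equal(nrow(hits), 12L)
  expect_equal(hits$percent_identity[1], 98.222)   # unrounded pass-through
  expect_equal(hits$read_start[1], 0L)
  expect_equal(hits$read_end[1], 250L)
  expect_equal(hits$subject_start[1], 99L)
  expect_equal(hits$subject_end[1], 349L)
  expect_identical(hits$strand[1], "+")
  # sstart > send encodes the minus strand, forward-normalized
  expect_identical(hits$strand[2], "-")
  expect_equal(hits$subject_start[2], 0L)
  expect_equal(hits$subject_end[2], 100L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(rows[1], "read9\tsubj1\tnot_a_number"), bad)
  expect_error(importBlastTabular(bad, "mito"), "line 2")

  # export inverts the import
  out <- tempfile(fileext = ".tsv")
  exportBlastTabular(hits, out)
  back <- importBlastTabular(out, db_id = "mito")
  expect_equal(back$subject_start, hits$subject_start)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$alignment_length, hits$alignment_length)
})

test_that("seed-and-extend scores equal the exact dynamic-programming optimum", {
  # independent oracle: Biostrings pairwiseAlignment under the same scoring
  set.seed(14)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  n_pairs <- 40
  agree <- 0
  for (i in 1:n_pairs) {
    subj <- random_dna(sample(2000:8000, 1))
    L <- nchar(subj)
    start <- sample(L - 299, 1)
    read <- substr(subj, start, start + 249)
    read <- mutate_seq(read, sample(250, sample(0:10, 1)))   # <= 4% divergence
    if (runif(1) < 0.3) {  # occasional short indel
      p <- sample(50:200, 1)
      read <- paste0(substr(read, 1, p), substr(read, p + 2, 250))
    }
    db <- make_db(c(s1 = subj))
    h <- alignReads(shotgunReads("r", read), db)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(read), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    if (nrow(h) == 1 && h$raw_score == Biostrings::score(oracle))
      agree <- agree + 1
  }
  expect_gte(agree / n_pairs, 0.99)
})
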