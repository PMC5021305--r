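# Shared fixtures and independent oracles for the test suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, positions) {
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  x <- strsplit(s, "")[[1]]
  x[positions] <- swap[x[positions]]
  paste(x, collapse = "")
}

# Independent tandem-repeat oracle: for every motif length and start, walk
# character by character to find the maximal periodic stretch; report the
# union of intervals whose total length reaches the threshold. O(n * 36).
ssr_oracle <- function(s, motif_lens = 1:6, min_total = 12) {
  x <- strsplit(toupper(s), "")[[1]]
  L <- length(x)
  covered <- rep(FALSE, L)
  for (m in motif_lens) {
    i <- 1
    while (i <= L - m) {
      e <- i
      while (e + m <= L && x[e + m] == x[e] && x[e] != "N") e <- e + 1
      run_end <- e + m - 1          # last position of the periodic stretch
      total <- run_end - i + 1
      if (total >= max(min_total, 2 * m) && total > m)
        covered[i:run_end] <- TRUE
      i <- if (e > i) e else i + 1
    }
  }
  covered
}

regions_to_coverage <- function(regions, L) {
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(regions)))
    covered[(regions$start[i] + 1):regions$end[i]] <- TRUE
  covered
}

# random alignment-hit table for filter/mask oracles
random_hits <- function(n, seq_ids = paste0("s", 1:4), seq_len = 2000,
                        db_id = "db") {
  start <- sample.int(seq_len - 300, n, replace = TRUE)
  len <- sample(150:300, n, replace = TRUE)
  data.frame(
    read_id = paste0("r", sample.int(n, n)),
    db_id = db_id,
    seq_id = sample(seq_ids, n, replace = TRUE),
    taxon_id = sample(c("taxA", "taxB", "taxC"), n, replace = TRUE),
    percent_identity = round(runif(n, 85, 100), 3),
    alignment_length = len,
    read_start = 0L, read_end = len,
    subject_start = start, subject_end = pmin(start + len, seq_len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    raw_score = round(runif(n, 50, 300)),
    evalue = 10^runif(n, -40, -6),
    stringsAsFactors = FALSE)
}

# minimal taxonomy with two congeneric chalcid species for LCA tests
mini_taxonomy <- function() {
  readTaxonomy(table = data.frame(
    taxon_id = c("Animalia", "Insecta", "Hymenoptera", "Chalcidoidea",
                 "Encarsia", "Encarsia_formosa", "Encarsia_sophia",
                 "Hemiptera", "Aphididae", "Aphis", "Aphis_gossypii"),
    rank = c("kingdom", "class", "order", "superfamily", "genus", "species",
             "species", "order", "family", "genus", "species"),
    parent_id = c(NA, "Animalia", "Insecta", "Hymenoptera", "Chalcidoidea",
                  "Encarsia", "Encarsia", "Insecta", "Hemiptera", "Aphididae",
                  "Aphis"),
    guild = c("other", "other", "other", "parasitoid", "parasitoid",
              "parasitoid", "parasitoid", "other", "herbivore", "herbivore",
              "herbivore"),
    tags = "", stringsAsFactors = FALSE))
}

# tiny two-member scenario used across simulator tests
tiny_scenario <- function(n_reads = 5000, seed = 7, intact_fraction = 0.5,
                          error_rate = 0.002) {
  members <- data.frame(
    taxon_id = c("HostX", "HostX", "PreyY"),
    seq_id = c("HostX_nuc", "HostX_mt", "PreyY_mt"),
    role = c("host_nuclear", "host_mt", "foreign_insect"),
    marker_class = c("nuclear_genome", "insect_mitogenome",
                     "insect_mitogenome"),
    genome_length = c(50000, 16000, 16000),
    read_fraction = c(0.993, 0.002, 0.005),
    stringsAsFactors = FALSE)
  communityScenario("HostX", members, intact_fraction = intact_fraction,
                    error_rate = error_rate, n_reads = n_reads,
                    read_length = 250, seed = seed)
}
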