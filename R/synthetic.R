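# Gut-content shotgun simulator: community scenarios, reference genomes at
# controlled divergence, host-dominated read libraries with truth tables.

#' @rdname communityScenario
#' @export
setClass("CommunityScenario", representation(
  focal_predator = "character",
  members = "data.frame",     # taxon_id, seq_id, role, marker_class,
                              # genome_length, read_fraction
  divergence = "matrix",      # percent, dimnames = seq_id; NA = unrelated
  fragment_mean = "numeric",
  fragment_sd = "numeric",
  fragment_max = "numeric",
  fragment_min = "numeric",
  intact_fraction = "numeric",
  host_mt_fraction = "numeric",
  error_rate = "numeric",
  n_reads = "numeric",
  read_length = "numeric",
  seed = "numeric"
))

MEMBER_ROLES <- c("host_nuclear", "host_mt", "foreign_insect", "symbiont")

setValidity("CommunityScenario", function(object) {
  msg <- character()
  m <- object@members
  need <- c("taxon_id", "seq_id", "role", "marker_class", "genome_length",
            "read_fraction")
  if (!all(need %in% names(m)))
    return(paste("members needs columns:", paste(need, collapse = ", ")))
  if (!all(m$role %in% MEMBER_ROLES))
    msg <- c(msg, "unknown member role")
  if (abs(sum(m$read_fraction) - 1) > 1e-9)
    msg <- c(msg, "member read_fractions must sum to 1")
  if (anyDuplicated(m$seq_id))
    msg <- c(msg, "member seq_ids must be unique")
  d <- object@divergence
  if (nrow(d) != nrow(m) || !identical(rownames(d), m$seq_id))
    msg <- c(msg, "divergence matrix must be indexed by member seq_ids")
  if (any(d < 0 | d > 40, na.rm = TRUE))
    msg <- c(msg, "divergence targets must lie in [0, 40] percent")
  if (object@fragment_max > 200 + 1e-9 &&
      any(m$role %in% c("foreign_insect", "symbiont")))
    msg <- c(msg)   # allowed, but see constructor default
  if (length(msg)) msg else TRUE
})

setMethod("show", "CommunityScenario", function(object) {
  m <- object@members
  cat("CommunityScenario: focal predator", object@focal_predator, "\n")
  cat(" ", format(object@n_reads, big.mark = ","), "reads x",
      object@read_length, "bp | host mt fraction",
      signif(object@host_mt_fraction, 3), "| error rate",
      object@error_rate, "| seed", object@seed, "\n")
  cat("  members:", sum(m$role == "foreign_insect"), "foreign insect,",
      sum(m$role == "symbiont"), "symbiont,",
      sum(m$read_fraction == 0), "reference-only\n")
})

#' Define a gut-content community scenario
#'
#' A scenario fixes everything the simulator needs: the focal predator, the
#' community members emitting reads (with genome lengths and read
#' fractions), target pairwise divergences among reference sequences,
#' the foreign template-length model, the host mitochondrial read fraction,
#' the sequencing error model and the library geometry.
#'
#' Members with `read_fraction = 0` are reference-only relatives: they join
#' the reference databases (at a controlled divergence from a community
#' member, straddling an identity threshold) without contributing reads.
#'
#' Foreign template lengths model digestion: an `intact_fraction` of
#' templates still spans the full read length, the rest follow a truncated
#' normal (`fragment_mean`, `fragment_sd`, hard bounds `fragment_min`,
#' `fragment_max`, default max 200 bp). Only intact templates can survive a
#' 225 bp minimum-overlap filter, so detected foreign reads are a fraction
#' of ingested ones — the regime the pipeline is designed for.
#'
#' @param focal_predator taxon id of the host predator.
#' @param members data.frame with `taxon_id`, `seq_id`, `role` (one of
#'   host_nuclear, host_mt, foreign_insect, symbiont), `marker_class`,
#'   `genome_length` (bp), `read_fraction`.
#' @param divergence percent divergence matrix over member `seq_id`s
#'   (NA = unrelated, generated independently). Default: all unrelated.
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max truncated
#'   normal parameters for degraded foreign template length (bp).
#' @param intact_fraction fraction of foreign templates of full read length.
#' @param host_mt_fraction fraction of all reads drawn from the host
#'   mitogenome; a warning is emitted outside the typical [0.0007, 0.007]
#'   band unless `check_host_mt = FALSE`.
#' @param error_rate per-base substitution error rate (Phred strings are
#'   written consistently with it).
#' @param n_reads,read_length library geometry (single-end).
#' @param seed RNG seed giving byte-identical output.
#' @param check_host_mt validate `host_mt_fraction` against the typical band.
#' @return a `CommunityScenario`.
#' @export
communityScenario <- function(focal_predator, members, divergence = NULL,
                              fragment_mean = 120, fragment_sd = 40,
                              fragment_min = 30, fragment_max = 200,
                              intact_fraction = 0.5,
                              host_mt_fraction = NULL,
                              error_rate = 0.002, n_reads = 1e6,
                              read_length = 250, seed = 1,
                              check_host_mt = TRUE) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  if (is.null(members$seq_id)) members$seq_id <- members$taxon_id
  if (is.null(divergence)) {
    divergence <- matrix(NA_real_, nrow(members), nrow(members),
                         dimnames = list(members$seq_id, members$seq_id))
    diag(divergence) <- 0
  }
  if (is.null(host_mt_fraction))
    host_mt_fraction <- sum(members$read_fraction[members$role == "host_mt"])
  if (check_host_mt &&
      (host_mt_fraction < 0.0007 || host_mt_fraction > 0.007))
    warning("host_mt_fraction ", signif(host_mt_fraction, 3),
            " lies outside the typical 0.07-0.7% band")
  new("CommunityScenario", focal_predator = focal_predator,
      members = members, divergence = divergence,
      fragment_mean = fragment_mean, fragment_sd = fragment_sd,
      fragment_max = fragment_max, fragment_min = fragment_min,
      intact_fraction = intact_fraction,
      host_mt_fraction = host_mt_fraction, error_rate = error_rate,
      n_reads = n_reads, read_length = read_length, seed = seed)
}

#' @rdname communityScenario
#' @export
scenarioMembers <- function(scenario) scenario@members

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# per-lineage mutation fractions p so that pairwise divergence under a star
# model, d_ij = p_i + p_j - (4/3) p_i p_j, matches the target matrix
solve_star_fractions <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(0)
  if (n == 2L) {
    d <- D[1, 2] / 100
    # symmetric pair: 2p - (4/3)p^2 = d
    p <- (2 - sqrt(4 - 16 * d / 3)) / (8 / 3)
    return(rep(p, 2))
  }
  target <- D / 100
  obj <- function(p) {
    m <- outer(p, p, `+`) - (4 / 3) * outer(p, p)
    sum((m - target)[upper.tri(target)]^2)
  }
  init <- rep(mean(target[upper.tri(target)]) / 2, n)
  fit <- optim(init, obj, method = "L-BFGS-B", lower = 0, upper = 0.45)
  fit$par
}

mutate_from <- function(ancestor, p) {
  if (p <= 0) return(ancestor)
  L <- nchar(ancestor)
  k <- round(p * L)
  if (k == 0L) return(ancestor)
  pos <- sample.int(L, k)
  x <- strsplit(ancestor, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  cur <- match(x[pos], bases)
  shift <- sample.int(3, k, replace = TRUE)
  x[pos] <- bases[((cur - 1 + shift) %% 4) + 1]
  paste(x, collapse = "")
}

#' Realized pairwise divergence between equal-length sequences
#'
#' @param seqs named character vector or `DNAStringSet` of equal-length
#'   sequences.
#' @return percent-divergence matrix.
#' @export
realizedDivergence <- function(seqs) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  raws <- lapply(seqs, charToRaw)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- 100 * mean(raws[[i]] != raws[[j]])
  }
  D
}

#' Generate reference genomes for a scenario
#'
#' Members connected by non-NA entries of the divergence matrix form a
#' lineage group: a common ancestor is drawn and each member mutated from it
#' so that realized pairwise divergence meets the target (within about half a
#' percentage point for additive targets; non-additive target matrices are
#' fit in least squares and the realized matrix should be inspected).
#' NA-linked members are generated independently. Deterministic under the
#' scenario seed.
#'
#' @param scenario a [communityScenario()].
#' @return list with `sequences` (named `DNAStringSet`) and `divergence`
#'   (realized percent matrix).
#' @export
generateGenomes <- function(scenario) {
  m <- scenario@members
  D <- scenario@divergence
  if (any(D < 0, na.rm = TRUE)) stop("negative divergence target")
  set.seed(scenario@seed)
  n <- nrow(m)
  seqs <- character(n)
  names(seqs) <- m$seq_id
  # connected components of the non-NA divergence graph
  adj <- !is.na(D); diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  for (g in unique(comp)) {
    idx <- which(comp == g)
    L <- unique(m$genome_length[idx])
    if (length(idx) == 1L) {
      seqs[idx] <- random_genome(m$genome_length[idx])
      next
    }
    if (length(L) != 1L)
      stop("related members (shared divergence group) must share genome_length")
    sub <- D[idx, idx, drop = FALSE]
    sub[is.na(sub)] <- mean(sub[upper.tri(sub)], na.rm = TRUE)
    p <- solve_star_fractions(sub)
    if (any(!is.finite(p))) stop("unattainable divergence target")
    anc <- random_genome(L)
    for (t in seq_along(idx)) seqs[idx[t]] <- mutate_from(anc, p[t])
  }
  sets <- Biostrings::DNAStringSet(seqs)
  groups <- split(seq_len(n), comp)
  real <- matrix(NA_real_, n, n, dimnames = list(m$seq_id, m$seq_id))
  diag(real) <- 0
  for (idx in groups) {
    if (length(idx) < 2L) next
    real[idx, idx] <- realizedDivergence(seqs[idx])
  }
  list(sequences = sets, divergence = real)
}

#' Simulate a gut-content shotgun library with ground truth
#'
#' Reads are allocated to members by a single multinomial draw over
#' `read_fraction`, positioned uniformly on the member genome, truncated to
#' the template length (host roles emit full-length templates; foreign and
#' symbiont templates follow the scenario's digestion model, so degraded
#' templates yield reads shorter than `read_length`), and perturbed by
#' substitution errors at `error_rate` with Phred strings consistent with
#' that rate. The truth table records source taxon, sequence, interval and
#' host status, one row per read, aligned with the reads.
#'
#' @param scenario a [communityScenario()].
#' @param genomes output of [generateGenomes()] for the same scenario.
#' @param fastq_path optional path; when given, the library is also written
#'   as FASTQ (byte-identical under a fixed seed).
#' @return list with `reads` ([ShotgunReads][shotgunReads()]) and `truth`
#'   (data.frame `read_id`, `taxon_id`, `seq_id`, `start`, `end`,
#'   `is_host`).
#' @export
simulateGutReads <- function(scenario, genomes, fastq_path = NULL) {
  m <- scenario@members
  n_reads <- scenario@n_reads
  empty_truth <- data.frame(read_id = character(), taxon_id = character(),
                            seq_id = character(), start = integer(),
                            end = integer(), is_host = logical(),
                            stringsAsFactors = FALSE)
  if (n_reads == 0)
    return(list(reads = shotgunReads(character(), character(), character()),
                truth = empty_truth))
  set.seed(scenario@seed %% 1000000000 + 7L)
  counts <- as.vector(rmultinom(1, n_reads, m$read_fraction))
  seq_chr <- as.character(genomes$sequences)[m$seq_id]
  q <- if (scenario@error_rate > 0)
    max(2L, min(41L, round(-10 * log10(scenario@error_rate)))) else 40L
  qchar <- rawToChar(as.raw(33L + q))
  all_seq <- vector("list", nrow(m))
  all_truth <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    k <- counts[i]
    if (k == 0L) next
    L <- m$genome_length[i]
    host_role <- m$role[i] %in% c("host_nuclear", "host_mt")
    if (host_role) {
      len <- rep(min(scenario@read_length, L), k)
    } else {
      intact <- runif(k) < scenario@intact_fraction
      frag <- round(rnorm(k, scenario@fragment_mean, scenario@fragment_sd))
      frag <- pmin(pmax(frag, scenario@fragment_min), scenario@fragment_max)
      len <- ifelse(intact, scenario@read_length, frag)
      len <- pmin(len, L)
    }
    start <- floor(runif(k) * (L - len + 1))   # 0-based
    reads <- substring(seq_chr[i], start + 1, start + len)
    all_seq[[i]] <- reads
    all_truth[[i]] <- data.frame(
      taxon_id = m$taxon_id[i], seq_id = m$seq_id[i],
      start = as.integer(start), end = as.integer(start + len),
      is_host = host_role, stringsAsFactors = FALSE)
  }
  seqs <- unlist(all_seq, use.names = FALSE)
  truth <- do.call(rbind, all_truth)
  ids <- sprintf("r%07d", seq_along(seqs))
  truth <- cbind(data.frame(read_id = ids, stringsAsFactors = FALSE), truth)
  rownames(truth) <- NULL
  if (scenario@error_rate > 0)
    seqs <- cpp_add_substitutions(seqs, scenario@error_rate)
  reads <- new("ShotgunReads", id = ids, sequence = seqs,
               quality = strrep(qchar, nchar(seqs)))
  if (!is.null(fastq_path)) writeFastq(reads, fastq_path)
  list(reads = reads, truth = truth)
}

#' Write a truth table as TSV
#'
#' @param truth truth data.frame from [simulateGutReads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Library profiles of a four-predator coccinellid/earwig field study:
# total reads after QC, host-mitochondrial read counts, and per-taxon
# foreign read counts recovered from the insect-mitogenome and
# bacterial-genome databases.
study_profiles <- function() {
  list(
    "Cycloneda sanguinea" = list(
      focal = "Cycloneda_sanguinea", total = 2837177, host_mt = 2061,
      insects = c(Doru_luteipes = 3, Harmonia_axyridis = 3),
      symbionts = c(Hamiltonella = 20, Spiroplasma = 1)),
    "Hippodamia convergens" = list(
      focal = "Hippodamia_convergens", total = 2647833, host_mt = 10506,
      insects = c(Dinocampus_coccinellae = 58, Coleomegilla_maculata = 57,
                  Harmonia_axyridis = 27, Spodoptera_frugiperda = 18,
                  Orius_insidiosus = 15, Coccinella_septempunctata = 11,
                  Euschistus = 6, Helicoverpa = 6),
      symbionts = c(Regiella_insecticola = 88, Rickettsia = 13,
                    Wolbachia = 1, Serratia = 8013)),
    "Harmonia axyridis" = list(
      focal = "Harmonia_axyridis", total = 3440064, host_mt = 9216,
      insects = c(Doru_luteipes = 8, Aphis_gossypii = 5),
      symbionts = c(Regiella_insecticola = 233, Hamiltonella = 29,
                    Rickettsiella = 12, Spiroplasma = 12, Wolbachia = 12,
                    Arsenophonus = 6, Serratia = 16814,
                    Serratia_symbiotica = 5)),
    "Doru luteipes" = list(
      focal = "Doru_luteipes", total = 2183902, host_mt = 17428,
      insects = c(Plutella_xylostella = 16, Harmonia_axyridis = 7,
                  Aphis_gossypii = 2),
      symbionts = c(Spiroplasma = 1419, Rickettsia = 642, Wolbachia = 640,
                    Nosema = 263, Serratia = 11095,
                    Serratia_symbiotica = 29, Regiella_insecticola = 21,
                    Arsenophonus = 9, Blattabacterium = 6,
                    Hamiltonella = 3)),
    "control" = list(
      focal = "Harmonia_axyridis", total = 3502252, host_mt = 7427,
      insects = c(), symbionts = c())
  )
}

#' Build a scenario emulating one library of the reference field study
#'
#' Returns a [communityScenario()] whose host-mitochondrial read fraction
#' and per-taxon foreign read fractions reproduce the named predator library
#' of a four-predator coccinellid/earwig gut-content study: a dominant host
#' nuclear background, host mtDNA at the observed fraction, tens-to-hundreds
#' of foreign insect reads and symbiont reads at the observed per-genus
#' counts. `"control"` is an unfed predator: host reads only, no foreign
#' members. Each foreign insect member gets a reference-only relative at 5%
#' divergence (straddling the 98% mitogenome identity threshold); distinct
#' taxa are generated as unrelated (independent) sequences.
#'
#' @param predator_name one of "Cycloneda sanguinea", "Hippodamia
#'   convergens", "Harmonia axyridis", "Doru luteipes", "control".
#' @param n_reads library size; the profile's read counts are scaled by
#'   `n_reads / total`. Default: the library's own total.
#' @param seed RNG seed.
#' @param host_nuclear_length,mt_length,symbiont_length stand-in genome
#'   lengths (bp) for the host nuclear background, mitogenomes and bacterial
#'   genomes.
#' @param relative_divergence percent divergence of reference-only relatives
#'   from their community member.
#' @return a `CommunityScenario`.
#' @export
scenarioFromStudyProfile <- function(predator_name, n_reads = NULL, seed = 1,
                                     host_nuclear_length = 1e6,
                                     mt_length = 16000,
                                     symbiont_length = 1e5,
                                     relative_divergence = 5) {
  profs <- study_profiles()
  if (!predator_name %in% names(profs))
    stop("unknown predator: ", predator_name, " (known: ",
         paste(names(profs), collapse = ", "), ")")
  p <- profs[[predator_name]]
  if (is.null(n_reads)) n_reads <- p$total
  mem <- list(data.frame(
    taxon_id = p$focal, seq_id = paste0(p$focal, "_nuc"),
    role = "host_nuclear", marker_class = "nuclear_genome",
    genome_length = host_nuclear_length, read_fraction = NA_real_,
    stringsAsFactors = FALSE))
  mem[[2]] <- data.frame(
    taxon_id = p$focal, seq_id = paste0(p$focal, "_mt"), role = "host_mt",
    marker_class = "insect_mitogenome", genome_length = mt_length,
    read_fraction = p$host_mt / p$total, stringsAsFactors = FALSE)
  for (tx in names(p$insects)) {
    mem[[length(mem) + 1L]] <- data.frame(
      taxon_id = tx, seq_id = paste0(tx, "_mt"), role = "foreign_insect",
      marker_class = "insect_mitogenome", genome_length = mt_length,
      read_fraction = p$insects[[tx]] / p$total, stringsAsFactors = FALSE)
    mem[[length(mem) + 1L]] <- data.frame(
      taxon_id = paste0(tx, "_relative"), seq_id = paste0(tx, "_rel_mt"),
      role = "foreign_insect", marker_class = "insect_mitogenome",
      genome_length = mt_length, read_fraction = 0, stringsAsFactors = FALSE)
  }
  for (tx in names(p$symbionts)) {
    mem[[length(mem) + 1L]] <- data.frame(
      taxon_id = tx, seq_id = paste0(tx, "_gen"), role = "symbiont",
      marker_class = "bacterial_genome", genome_length = symbiont_length,
      read_fraction = p$symbionts[[tx]] / p$total, stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, mem)
  members$read_fraction[1] <- 1 - sum(members$read_fraction, na.rm = TRUE)
  # each foreign insect mitogenome pairs with its reference-only relative at
  # an exact controlled divergence; all other member pairs are unrelated
  # (independent random sequences), keeping every target attainable
  D <- matrix(NA_real_, nrow(members), nrow(members),
              dimnames = list(members$seq_id, members$seq_id))
  diag(D) <- 0
  for (tx in names(p$insects)) {
    a <- paste0(tx, "_mt"); b <- paste0(tx, "_rel_mt")
    D[a, b] <- D[b, a] <- relative_divergence
  }
  communityScenario(
    focal_predator = p$focal, members = members, divergence = D,
    host_mt_fraction = p$host_mt / p$total, n_reads = n_reads, seed = seed,
    check_host_mt = FALSE)
}

#' Build reference databases and a taxonomy for a scenario
#'
#' Convenience for end-to-end validation: groups the scenario members by
#' marker class into [ReferenceDatabase-class] objects (host nuclear
#' background excluded — gut-content references cover markers, not the
#' host's whole nuclear genome) and derives a minimal taxonomy (insect
#' members as species under one class; symbionts as genera under Bacteria).
#'
#' @param scenario a [communityScenario()].
#' @param genomes output of [generateGenomes()].
#' @param policies named list of [MatchPolicy()] per marker class.
#' @return list with `databases` (named list) and `taxonomy`.
#' @export
scenarioDatabases <- function(scenario, genomes,
                              policies = defaultPolicies()) {
  m <- scenario@members
  keep <- m$role != "host_nuclear"
  dbs <- list()
  for (mc in unique(m$marker_class[keep])) {
    rows <- m[keep & m$marker_class == mc, , drop = FALSE]
    seqs <- genomes$sequences[rows$seq_id]
    md <- data.frame(seq_id = rows$seq_id, taxon_id = rows$taxon_id,
                     stringsAsFactors = FALSE)
    dbs[[mc]] <- loadDatabase(seqs, md, policies[[mc]], db_id = mc,
                              marker_class = mc)
  }
  tax_rows <- list(
    data.frame(taxon_id = "Animalia", rank = "kingdom",
               parent_id = NA_character_, guild = "other", tags = "",
               stringsAsFactors = FALSE),
    data.frame(taxon_id = "Insecta", rank = "class", parent_id = "Animalia",
               guild = "other", tags = "", stringsAsFactors = FALSE),
    data.frame(taxon_id = "Bacteria", rank = "kingdom",
               parent_id = NA_character_, guild = "other", tags = "",
               stringsAsFactors = FALSE))
  for (i in seq_len(nrow(m))) {
    tid <- m$taxon_id[i]
    if (tid %in% vapply(tax_rows, function(x) x$taxon_id, character(1)))
      next
    if (m$role[i] == "symbiont") {
      tax_rows[[length(tax_rows) + 1L]] <- data.frame(
        taxon_id = tid, rank = "genus", parent_id = "Bacteria",
        guild = "symbiont", tags = "", stringsAsFactors = FALSE)
    } else {
      guild <- if (tid == scenario@focal_predator) "focal_predator"
               else "herbivore"
      tax_rows[[length(tax_rows) + 1L]] <- data.frame(
        taxon_id = tid, rank = "species", parent_id = "Insecta",
        guild = guild, tags = "", stringsAsFactors = FALSE)
    }
  }
  list(databases = dbs,
       taxonomy = readTaxonomy(table = do.call(rbind, tax_rows)))
}
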