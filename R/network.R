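# Trophic-network inference from per-database detections: cross-database
# merging, direct predation edges, indirect (symbiont/parasitoid-mediated)
# edges, summaries and export.

INSECT_MARKER_CLASSES <- c("insect_mitogenome", "cox1_barcode",
                           "nuclear_genome")

#' @rdname buildTrophicNetwork
#' @export
setClass("TrophicNetwork", representation(
  nodes = "data.frame",   # taxon_id, guild
  edges = "data.frame"    # predator, prey, edge_type, guild_class,
                          # support_reads, evidence, note
))

setValidity("TrophicNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    endpoints <- unique(c(e$predator, e$prey))
    if (!all(endpoints %in% object@nodes$taxon_id))
      msg <- c(msg, "every edge endpoint must be a node")
    if (anyDuplicated(paste(e$predator, e$prey, e$edge_type)))
      msg <- c(msg, "duplicate (predator, prey, edge_type) edges")
    if (any(e$support_reads < 1))
      msg <- c(msg, "edge support_reads must be >= 1")
    if (!all(e$edge_type %in% c("direct", "inferred")))
      msg <- c(msg, "edge_type must be direct or inferred")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrophicNetwork", function(object) {
  e <- object@edges
  cat("TrophicNetwork:", nrow(object@nodes), "nodes,",
      sum(e$edge_type == "direct"), "direct +",
      sum(e$edge_type == "inferred"), "inferred edges\n")
})

#' @rdname buildTrophicNetwork
#' @export
networkEdges <- function(network) network@edges

#' @rdname buildTrophicNetwork
#' @export
networkNodes <- function(network) network@nodes

#' Read symbiont/parasitoid association rules
#'
#' Each rule links an association tag carried by detected taxa (e.g.
#' `aphid_specific_symbiont`) to the prey group whose consumption it implies
#' (e.g. Aphididae), with an evidence type of `symbiont` or `parasitoid`.
#' Symbiont detections both trigger and support inferred predation edges;
#' parasitoid detections trigger them but contribute no read support (a
#' parasitoid read may also reflect direct predation on the free-living
#' stage, so its counts are not biomass-flow evidence).
#'
#' @param path TSV with columns `trigger_tag`, `implied_prey_group`,
#'   `evidence_type`; or pass `table` directly.
#' @param table data.frame alternative to `path`.
#' @return validated rules data.frame.
#' @export
readAssociationRules <- function(path = NULL, table = NULL) {
  if (is.null(table)) table <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("trigger_tag", "implied_prey_group", "evidence_type")
  if (!all(need %in% names(table)))
    stop("rules need columns: ", paste(need, collapse = ", "))
  if (!all(table$evidence_type %in% c("symbiont", "parasitoid")))
    stop("evidence_type must be symbiont or parasitoid")
  table
}

#' Merge detections of the same lineage across insect databases
#'
#' Detections from the insect databases (mitogenome, cox1 barcode, nuclear
#' genome) often hit the same prey at different resolutions — a genus-level
#' barcode match and a species-level mitogenome match. Detections whose taxa
#' are identical, or where one is an ancestor of the other, are merged into
#' the most specific taxon with read support summed. An ancestor folds into a
#' descendant only when the descendant is unambiguous (exactly one maximal
#' descendant among that predator's detections).
#'
#' @param detections detection table (see [tallyDetections()]) with a
#'   `marker_class` column; non-insect classes are ignored here.
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @return data.frame `predator_id`, `taxon_id`, `rank`, `support_reads`,
#'   `evidence` (semicolon-joined `db_id:count`).
#' @export
mergeCrossDatabase <- function(detections, taxonomy) {
  det <- detections[detections$marker_class %in% INSECT_MARKER_CLASSES, ,
                    drop = FALSE]
  if (nrow(det) == 0L)
    return(data.frame(predator_id = character(), taxon_id = character(),
                      rank = character(), support_reads = integer(),
                      evidence = character(), stringsAsFactors = FALSE))
  out <- lapply(split(det, det$predator_id), function(d) {
    taxa <- unique(d$taxon_id)
    # map each taxon to its unique most-specific descendant among taxa
    target <- setNames(taxa, taxa)
    for (t in taxa) {
      desc <- taxa[taxa != t & isDescendant(taxonomy, taxa, t)]
      if (length(desc)) {
        # keep only maximal (most specific) descendants
        maximal <- desc[!vapply(desc, function(x)
          any(desc != x & isDescendant(taxonomy, desc, x)), logical(1))]
        if (length(maximal) == 1L) target[t] <- maximal
      }
    }
    # resolve chains (genus -> species via intermediate)
    for (t in taxa) {
      while (target[[target[[t]]]] != target[[t]]) target[t] <- target[[target[[t]]]]
    }
    grp <- split(seq_len(nrow(d)), unname(target[d$taxon_id]))
    do.call(rbind, lapply(names(grp), function(tax) {
      idx <- grp[[tax]]
      data.frame(predator_id = d$predator_id[1], taxon_id = tax,
                 rank = taxonRank(taxonomy, tax),
                 support_reads = sum(d$read_count[idx]),
                 evidence = paste(paste0(d$db_id[idx], ":", d$read_count[idx]),
                                  collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$predator_id, -out$support_reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build direct predation edges from merged insect detections
#'
#' One direct edge per merged foreign insect taxon. The edge is classed
#' `intraguild` when the prey's guild belongs to the configured predator
#' guild list (predation among species sharing the prey base), else
#' `extraguild`. Prey whose guild is `parasitoid` (a species-level parasitoid
#' recovered from insect markers) is emitted as a direct edge with a note
#' that direct consumption versus parasitism of the predator cannot be
#' distinguished from reads alone.
#'
#' @param merged output of [mergeCrossDatabase()]; must not contain the focal
#'   predator itself (host reads are separated upstream).
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param predator_guilds guilds counted as "the predator guild" for
#'   intraguild classification.
#' @return edge data.frame.
#' @export
buildDirectEdges <- function(merged, taxonomy,
                             predator_guilds = c("focal_predator",
                                                 "other_predator")) {
  if (nrow(merged) == 0L)
    return(data.frame(predator = character(), prey = character(),
                      edge_type = character(), guild_class = character(),
                      support_reads = integer(), evidence = character(),
                      note = character(), stringsAsFactors = FALSE))
  guild <- taxonGuild(taxonomy, merged$taxon_id)
  data.frame(
    predator = merged$predator_id,
    prey = merged$taxon_id,
    edge_type = "direct",
    guild_class = ifelse(guild %in% predator_guilds, "intraguild",
                         "extraguild"),
    support_reads = merged$support_reads,
    evidence = merged$evidence,
    note = ifelse(guild == "parasitoid",
                  "direct_consumption_or_parasitism_uncertain", ""),
    stringsAsFactors = FALSE)
}

#' Infer indirect predation edges from symbiont and parasitoid detections
#'
#' For each predator and implied prey group: if at least one detection
#' carries a rule's trigger tag and no direct edge already reaches a taxon
#' within the group, one inferred edge predator -> group is emitted.
#' Support is the sum of read counts of triggering symbiont detections;
#' parasitoid triggers are listed as evidence but contribute no support
#' reads.
#'
#' @param detections full detection table (all databases).
#' @param rules association-rule table ([readAssociationRules()]).
#' @param direct_edges edge data.frame from [buildDirectEdges()].
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @return edge data.frame of inferred edges.
#' @export
inferIndirectEdges <- function(detections, rules, direct_edges, taxonomy) {
  empty <- data.frame(predator = character(), prey = character(),
                      edge_type = character(), guild_class = character(),
                      support_reads = integer(), evidence = character(),
                      note = character(), stringsAsFactors = FALSE)
  if (nrow(detections) == 0L || nrow(rules) == 0L) return(empty)
  tags <- lapply(setNames(nm = unique(detections$taxon_id)),
                 function(t) taxonTags(taxonomy, t))
  out <- list()
  for (pred in unique(detections$predator_id)) {
    d <- detections[detections$predator_id == pred, , drop = FALSE]
    for (group in unique(rules$implied_prey_group)) {
      rg <- rules[rules$implied_prey_group == group, , drop = FALSE]
      trig <- vapply(d$taxon_id, function(t)
        any(rg$trigger_tag %in% tags[[t]]), logical(1))
      if (!any(trig)) next
      de <- direct_edges[direct_edges$predator == pred, , drop = FALSE]
      covered <- nrow(de) > 0 &&
        any(isDescendant(taxonomy, de$prey, group) | de$prey == group)
      if (covered) next
      dt <- d[trig, , drop = FALSE]
      ev_type <- vapply(dt$taxon_id, function(t) {
        r <- rg[rg$trigger_tag %in% tags[[t]], , drop = FALSE]
        if (any(r$evidence_type == "symbiont")) "symbiont" else "parasitoid"
      }, character(1))
      # a taxon detected in several databases counts once per detection row;
      # support sums symbiont-triggered read counts only
      support <- sum(dt$read_count[ev_type == "symbiont"])
      if (support < 1L) support <- 1L   # parasitoid-only trigger
      out[[length(out) + 1L]] <- data.frame(
        predator = pred, prey = group, edge_type = "inferred",
        guild_class = ifelse(taxonGuild(taxonomy, group) %in%
                               c("focal_predator", "other_predator"),
                             "intraguild", "extraguild"),
        support_reads = support,
        evidence = paste(paste0(dt$db_id, ":", dt$taxon_id, ":",
                                dt$read_count, ":", ev_type),
                         collapse = ";"),
        note = "", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Assemble a qualitative trophic network from detections
#'
#' Runs [mergeCrossDatabase()], [buildDirectEdges()] and
#' [inferIndirectEdges()] per predator and returns a validated network whose
#' nodes carry guild annotations.
#'
#' @param detections detection table for one or more predators (with
#'   `marker_class`).
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param rules association rules ([readAssociationRules()]); NULL disables
#'   inferred edges.
#' @param predator_guilds see [buildDirectEdges()].
#' @return a `TrophicNetwork`.
#' @export
buildTrophicNetwork <- function(detections, taxonomy, rules = NULL,
                                predator_guilds = c("focal_predator",
                                                    "other_predator")) {
  merged <- mergeCrossDatabase(detections, taxonomy)
  direct <- buildDirectEdges(merged, taxonomy, predator_guilds)
  inferred <- if (!is.null(rules))
    inferIndirectEdges(detections, rules, direct, taxonomy)
  else direct[0, , drop = FALSE]
  edges <- rbind(direct, inferred)
  nodes <- unique(c(edges$predator, edges$prey,
                    unique(detections$predator_id)))
  nodes <- data.frame(taxon_id = nodes,
                      guild = taxonGuild(taxonomy, nodes),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("TrophicNetwork", nodes = nodes, edges = edges)
}

#' Summarize a trophic network
#'
#' Per predator: direct and inferred link counts and intraguild prey richness
#' split into coccinellid (prey within Coccinellidae) and other predators.
#' Pooled across predators: the fraction of direct links resolved to species
#' or genus (taxonomic resolution of the method) and the number of unique
#' species- or genus-level taxa assigned any trophic linkage — direct prey,
#' plus species/genus parasitoid detections, plus rule-triggering symbiont
#' taxa, deduplicated across predators.
#'
#' @param network a `TrophicNetwork`.
#' @param detections the detection table the network was built from.
#' @param taxonomy a [Taxonomy][readTaxonomy()].
#' @param rules association rules used for the network (may be NULL).
#' @param coccinellid_clade clade defining the "coccinellid" intraguild
#'   subtype.
#' @return list with `per_predator` (data.frame) and `pooled` (list:
#'   `n_direct_links`, `species_or_genus_links`, `species_or_genus_pct`,
#'   `linked_species_genus_taxa`).
#' @export
summarizeNetwork <- function(network, detections, taxonomy, rules = NULL,
                             coccinellid_clade = "Coccinellidae") {
  e <- network@edges
  preds <- unique(detections$predator_id)
  per <- do.call(rbind, lapply(preds, function(p) {
    ep <- e[e$predator == p, , drop = FALSE]
    intra <- ep[ep$edge_type == "direct" & ep$guild_class == "intraguild", ,
                drop = FALSE]
    is_cocc <- if (nrow(intra) && coccinellid_clade %in%
                   taxonomyTable(taxonomy)$taxon_id)
      isDescendant(taxonomy, intra$prey, coccinellid_clade)
    else logical(nrow(intra))
    data.frame(predator_id = p,
               direct_links = sum(ep$edge_type == "direct"),
               inferred_links = sum(ep$edge_type == "inferred"),
               intraguild_richness = nrow(intra),
               intraguild_coccinellid = sum(is_cocc),
               intraguild_other = sum(!is_cocc),
               stringsAsFactors = FALSE)
  }))
  direct <- e[e$edge_type == "direct", , drop = FALSE]
  sg_rank <- taxonRank(taxonomy, direct$prey) %in% c("species", "genus")
  # unique species/genus taxa with any trophic linkage
  linked <- unique(direct$prey[sg_rank])
  par_det <- detections[detections$marker_class == "parasitoid_markers" &
                          detections$rank %in% c("species", "genus"), ,
                        drop = FALSE]
  linked <- union(linked, par_det$taxon_id)
  if (!is.null(rules)) {
    sym_taxa <- unique(detections$taxon_id[vapply(detections$taxon_id,
      function(t) any(rules$trigger_tag %in% taxonTags(taxonomy, t)),
      logical(1))])
    sym_taxa <- sym_taxa[taxonRank(taxonomy, sym_taxa) %in%
                           c("species", "genus")]
    linked <- union(linked, sym_taxa)
  }
  pooled <- list(
    n_direct_links = nrow(direct),
    species_or_genus_links = sum(sg_rank),
    species_or_genus_pct = if (nrow(direct))
      round(100 * sum(sg_rank) / nrow(direct)) else NA_real_,
    linked_species_genus_taxa = length(linked))
  list(per_predator = per, pooled = pooled)
}

#' Export and import a trophic network
#'
#' Formats: `tsv` (lossless round trip via [importNetworkTsv()]), `dot`
#' (Graphviz; inferred edges rendered dashed) and `graphml` (via igraph).
#' Edge attributes always include type, guild class and read support.
#'
#' @param network a `TrophicNetwork`.
#' @param path output file.
#' @param format `"tsv"`, `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(network, path, format = c("tsv", "dot", "graphml")) {
  format <- match.arg(format)
  e <- network@edges
  n <- network@nodes
  if (format == "tsv") {
    df <- e
    df$predator_guild <- n$guild[match(df$predator, n$taxon_id)]
    df$prey_guild <- n$guild[match(df$prey, n$taxon_id)]
    # isolated nodes (e.g. a control predator with no links) are preserved
    # as pseudo-rows with edge_type "node" so the round trip is lossless
    lone <- n[!n$taxon_id %in% c(e$predator, e$prey), , drop = FALSE]
    if (nrow(lone)) {
      df <- rbind(df, data.frame(
        predator = lone$taxon_id, prey = "", edge_type = "node",
        guild_class = "", support_reads = 0L, evidence = "", note = "",
        predator_guild = lone$guild, prey_guild = "",
        stringsAsFactors = FALSE))
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "dot") {
    lines <- c("digraph trophic {")
    for (i in seq_len(nrow(n)))
      lines <- c(lines, sprintf('  "%s" [guild="%s"];', n$taxon_id[i],
                                n$guild[i]))
    for (i in seq_len(nrow(e))) {
      style <- if (e$edge_type[i] == "inferred") "dashed" else "solid"
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [style=%s, label="%d", guild_class="%s"];',
        e$predator[i], e$prey[i], style, e$support_reads[i],
        e$guild_class[i]))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = e$predator, to = e$prey,
                     edge_type = e$edge_type, guild_class = e$guild_class,
                     support_reads = e$support_reads,
                     stringsAsFactors = FALSE),
      vertices = data.frame(name = n$taxon_id, guild = n$guild,
                            stringsAsFactors = FALSE),
      directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportNetwork
#' @export
importNetworkTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  if (nrow(df) == 0L) {
    nodes <- data.frame(taxon_id = character(), guild = character(),
                        stringsAsFactors = FALSE)
    edges <- data.frame(predator = character(), prey = character(),
                        edge_type = character(), guild_class = character(),
                        support_reads = integer(), evidence = character(),
                        note = character(), stringsAsFactors = FALSE)
    return(new("TrophicNetwork", nodes = nodes, edges = edges))
  }
  df$note[is.na(df$note)] <- ""
  lone <- df[df$edge_type == "node", , drop = FALSE]
  df <- df[df$edge_type != "node", , drop = FALSE]
  nodes <- unique(rbind(
    data.frame(taxon_id = df$predator, guild = df$predator_guild,
               stringsAsFactors = FALSE),
    data.frame(taxon_id = df$prey, guild = df$prey_guild,
               stringsAsFactors = FALSE),
    data.frame(taxon_id = lone$predator, guild = lone$predator_guild,
               stringsAsFactors = FALSE)))
  edges <- df[, c("predator", "prey", "edge_type", "guild_class",
                  "support_reads", "evidence", "note")]
  rownames(nodes) <- rownames(edges) <- NULL
  new("TrophicNetwork", nodes = nodes, edges = edges)
}
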