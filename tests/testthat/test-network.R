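# Cross-database merging, direct/inferred edges, summaries, export formats.

test_that("cross-database detections merge into the most specific taxon", {
  ex <- exampleGutStudy()
  merged <- mergeCrossDatabase(ex$detections, ex$taxonomy)

  # genus-level barcode and species-level mitogenome/genome hits fold into
  # the species, with summed support
  ha <- merged[merged$predator_id == "Harmonia_axyridis", ]
  expect_equal(ha$support_reads[ha$taxon_id == "Aphis_gossypii"], 12L)
  expect_false("Aphis" %in% ha$taxon_id)
  # disjoint taxa stay separate
  expect_true("Doru_luteipes" %in% ha$taxon_id)
  expect_equal(nrow(ha), 2L)
  # identical species in two databases merge to one entry, summed
  dl <- merged[merged$predator_id == "Doru_luteipes", ]
  expect_equal(dl$support_reads[dl$taxon_id == "Plutella_xylostella"], 17L)
  # an ancestor with no detected descendant is untouched
  expect_equal(dl$support_reads[dl$taxon_id == "Aphididae"], 2L)
  # parasitoid/bacterial/rRNA detections never enter the merge
  expect_false(any(merged$taxon_id %in% c("Chalcidoidea", "Serratia",
                                          "Ascomycota")))
})

test_that("direct edges carry guild classes and parasitoid caveats", {
  ex <- exampleGutStudy()
  merged <- mergeCrossDatabase(ex$detections, ex$taxonomy)
  edges <- buildDirectEdges(merged, ex$taxonomy)
  cy <- edges[edges$predator == "Cycloneda_sanguinea", ]
  expect_equal(nrow(cy), 2L)
  expect_true(all(cy$guild_class == "intraguild"))
  dl <- edges[edges$predator == "Doru_luteipes", ]
  expect_equal(nrow(dl), 3L)
  expect_setequal(dl$prey, c("Plutella_xylostella", "Harmonia_axyridis",
                             "Aphididae"))
  # the coccinellid parasitoid is a direct edge flagged as uncertain
  hc <- edges[edges$predator == "Hippodamia_convergens", ]
  expect_match(hc$note[hc$prey == "Dinocampus_coccinellae"], "uncertain")
  expect_equal(nrow(buildDirectEdges(merged[0, ], ex$taxonomy)), 0L)
})

test_that("indirect edges appear only without direct evidence for the group", {
  ex <- exampleGutStudy()
  merged <- mergeCrossDatabase(ex$detections, ex$taxonomy)
  direct <- buildDirectEdges(merged, ex$taxonomy)
  inferred <- inferIndirectEdges(ex$detections, ex$rules, direct,
                                 ex$taxonomy)
  # an aphid symbiont without aphid DNA implies aphid predation
  cy <- inferred[inferred$predator == "Cycloneda_sanguinea", ]
  expect_equal(nrow(cy), 1L)
  expect_identical(cy$prey, "Aphididae")
  expect_equal(cy$support_reads, 20L)   # symbiont reads only
  # parasitoid triggers add evidence but no support
  hc <- inferred[inferred$predator == "Hippodamia_convergens", ]
  expect_equal(hc$support_reads, 88L)
  expect_match(hc$evidence, "Aphidiinae")
  # direct aphid evidence suppresses the inferred edge
  expect_false("Harmonia_axyridis" %in% inferred$predator)
  expect_false("Doru_luteipes" %in% inferred$predator)
  # no triggering detections, no edges
  none <- ex$detections[ex$detections$taxon_id == "Serratia", ]
  expect_equal(nrow(inferIndirectEdges(none, ex$rules, direct[0, ],
                                       ex$taxonomy)), 0L)
})

test_that("a new direct edge to the group removes the inferred edge on rebuild", {
  ex <- exampleGutStudy()
  net1 <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
  e1 <- networkEdges(net1)
  expect_true(any(e1$predator == "Cycloneda_sanguinea" &
                    e1$prey == "Aphididae" & e1$edge_type == "inferred"))
  # spike an aphid detection into the coccinellid's insect databases
  extra <- data.frame(predator_id = "Cycloneda_sanguinea", db_id = "mito",
                      marker_class = "insect_mitogenome",
                      taxon_id = "Aphis_gossypii", rank = "species",
                      read_count = 6L, stringsAsFactors = FALSE)
  det2 <- rbind(ex$detections[, names(extra)], extra)
  net2 <- buildTrophicNetwork(det2, ex$taxonomy, ex$rules)
  e2 <- networkEdges(net2)
  expect_true(any(e2$predator == "Cycloneda_sanguinea" &
                    e2$prey == "Aphis_gossypii" & e2$edge_type == "direct"))
  expect_false(any(e2$predator == "Cycloneda_sanguinea" &
                     e2$edge_type == "inferred"))
  # and no inferred edge is ever duplicated by a rebuild
  expect_equal(anyDuplicated(e2[, c("predator", "prey", "edge_type")]), 0L)
})

test_that("edge support equals the sum of contributing detection counts", {
  ex <- exampleGutStudy()
  net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
  e <- networkEdges(net)
  direct <- e[e$edge_type == "direct", ]
  insect <- ex$detections[ex$detections$marker_class %in%
                            c("insect_mitogenome", "cox1_barcode",
                              "nuclear_genome"), ]
  expect_equal(sum(direct$support_reads), sum(insect$read_count))
})

test_that("network summary reproduces link counts and resolution", {
  ex <- exampleGutStudy()
  net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
  s <- summarizeNetwork(net, ex$detections, ex$taxonomy, ex$rules)
  per <- s$per_predator
  expect_equal(per$direct_links[per$predator_id == "Hippodamia_convergens"],
               8L)
  expect_equal(per$intraguild_coccinellid[per$predator_id ==
                                            "Hippodamia_convergens"], 3L)
  expect_equal(s$pooled$species_or_genus_pct, 93)
  # a single-edge network at species rank scores 100%
  one <- ex$detections[ex$detections$predator_id == "Harmonia_axyridis" &
                         ex$detections$taxon_id == "Doru_luteipes", ]
  net1 <- buildTrophicNetwork(one, ex$taxonomy, NULL)
  s1 <- summarizeNetwork(net1, one, ex$taxonomy)
  expect_equal(s1$pooled$species_or_genus_pct, 100)
})

test_that("TSV export round-trips the network losslessly", {
  ex <- exampleGutStudy()
  net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
  path <- tempfile(fileext = ".tsv")
  exportNetwork(net, path, "tsv")
  back <- importNetworkTsv(path)
  ord <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(networkEdges(back)), ord(networkEdges(net)))
  expect_equal(ord(networkNodes(back)), ord(networkNodes(net)))
})

test_that("DOT output dashes inferred edges; GraphML loads in igraph", {
  ex <- exampleGutStudy()
  net <- buildTrophicNetwork(ex$detections, ex$taxonomy, ex$rules)
  dot <- tempfile(fileext = ".dot")
  exportNetwork(net, dot, "dot")
  lines <- readLines(dot)
  inferred_lines <- grep("style=dashed", lines, value = TRUE)
  expect_length(inferred_lines,
                sum(networkEdges(net)$edge_type == "inferred"))
  expect_true(any(grepl("Cycloneda_sanguinea.*Aphididae.*dashed",
                        inferred_lines)))
  gml <- tempfile(fileext = ".graphml")
  exportNetwork(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
  expect_error(exportNetwork(net, tempfile(), "gexf"), "arg")
})

test_that("an empty network exports valid documents", {
  empty <- buildTrophicNetwork(
    exampleGutStudy()$detections[0, ], exampleGutStudy()$taxonomy, NULL)
  tsv <- tempfile(fileext = ".tsv")
  exportNetwork(empty, tsv, "tsv")
  expect_equal(nrow(networkEdges(importNetworkTsv(tsv))), 0L)
  dot <- tempfile(fileext = ".dot")
  exportNetwork(empty, dot, "dot")
  expect_identical(readLines(dot), c("digraph trophic {", "}"))
})
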