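test_that("save/load round trip is lossless and byte-stable", {
  for (seed in c(11, 12, 13, 14, 15, 16, 17, 18, 19, 20)) {
    g <- generate_graph(tiny_config(seed))$graph
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    save_graph(g, d1)
    g2 <- load_graph(d1)
    expect_identical(g2, g)
    save_graph(g2, d2)
    for (f in basename(unname(raredr:::graph_files()))) {
      expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)))
    }
  }
})

test_that("unicode disease names survive the round trip", {
  g <- toy_direct_graph()
  g$diseases$name[1] <- "Dejerine–Sottas étude α"
  g <- knowledge_graph(g$diseases, g$drugs, g$nodes, g$edges)
  d <- withr::local_tempdir()
  save_graph(g, d)
  expect_identical(load_graph(d)$diseases$name[1], g$diseases$name[1])
})

test_that("referential integrity violations are rejected with the endpoint named", {
  g <- toy_direct_graph()
  edges <- g$edges
  edges$disease_gene <- rbind(edges$disease_gene,
                              data.frame(disease_id = "C9999999", feature_id = "G1"))
  expect_error(knowledge_graph(g$diseases, g$drugs, g$nodes, edges),
               "C9999999", class = "raredr_validation_error")
  edges <- g$edges
  edges$drug_target <- rbind(edges$drug_target,
                             data.frame(drug_id = "D1", node_id = "P404"))
  expect_error(knowledge_graph(g$diseases, g$drugs, g$nodes, edges),
               "P404", class = "raredr_validation_error")
})

test_that("empty edge sets with non-empty node tables give a valid graph with empty profiles", {
  g <- knowledge_graph(
    diseases = data.frame(id = "R1", name = "r", is_rare = TRUE,
                          prevalence_class = "unknown",
                          prevalence_geography = "Worldwide"),
    drugs = data.frame(id = "D1", name = "d", atc_codes = ""),
    nodes = data.frame(id = "G1", role = "gene"))
  p <- feature_profile(g, "R1")
  expect_true(all(lengths(p) == 0))
})

test_that("Orphanet unknown prevalence variants collapse; malformed classes error", {
  d <- data.frame(id = c("A1", "A2", "A3"), name = "x", is_rare = TRUE,
                  prevalence_class = c("Null", "Not yet documented", "Unknown"),
                  prevalence_geography = "Worldwide")
  g <- knowledge_graph(d, data.frame(id = character(), name = character(),
                                     atc_codes = character()),
                       data.frame(id = character(), role = character()))
  expect_identical(unique(g$diseases$prevalence_class), "unknown")
  d$prevalence_class <- "1 in a million"
  expect_error(knowledge_graph(d, g$drugs, g$nodes),
               "prevalence", class = "raredr_validation_error")
})

test_that("ATC codes must be 7 characters with a valid level-1 letter", {
  base <- toy_direct_graph()
  drugs <- base$drugs
  drugs$atc_codes <- "X07AG02"
  expect_error(knowledge_graph(base$diseases, drugs, base$nodes, base$edges),
               class = "raredr_validation_error")
  drugs$atc_codes <- "C07A"
  expect_error(knowledge_graph(base$diseases, drugs, base$nodes, base$edges),
               class = "raredr_validation_error")
})

test_that("feature profiles equal the disease's edge neighbourhoods", {
  g <- toy_direct_graph()
  p <- feature_profile(g, "R1")
  expect_identical(p$genes, "G1")
  expect_identical(p$symptoms, "S1")
  expect_identical(p$proteins, character())
  expect_error(feature_profile(g, "nope"), class = "raredr_lookup_error")

  gen <- generate_graph(tiny_config(31))$graph
  for (feat in feature_kinds()) {
    nm <- paste0("disease_", feat)
    plural <- c(gene = "genes", symptom = "symptoms", protein = "proteins",
                pathway = "pathways", variant = "variants")[[feat]]
    total <- sum(vapply(gen$diseases$id,
                        function(id) length(feature_profile(gen, id)[[plural]]),
                        integer(1)))
    expect_identical(total, nrow(gen$edges[[nm]]))
  }
})

test_that("ppi neighbour queries are order-independent", {
  g <- generate_graph(tiny_config(32))$graph
  e <- g$edges$ppi
  prots <- unique(c(e$protein_a, e$protein_b))
  for (p in prots) {
    for (q in ppi_neighbors(g, p)) {
      expect_true(p %in% ppi_neighbors(g, q))
    }
  }
})

test_that("duplicate edges are deduplicated with a warning", {
  base <- toy_direct_graph()
  edges <- base$edges
  edges$disease_gene <- rbind(edges$disease_gene, edges$disease_gene)
  expect_warning(
    g <- knowledge_graph(base$diseases, base$drugs, base$nodes, edges),
    "duplicate")
  expect_identical(nrow(g$edges$disease_gene), 1L)
})

test_that("loading a directory with a missing file is a configuration error", {
  d <- withr::local_tempdir()
  save_graph(toy_direct_graph(), d)
  unlink(file.path(d, "gda.tsv"))
  expect_error(load_graph(d), "gda", class = "raredr_config_error")
})
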