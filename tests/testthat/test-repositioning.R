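test_that("direct approach follows the gene-protein-target chain", {
  g <- toy_direct_graph()
  expect_identical(direct_approach(g, "R1"), "D1")
  expect_identical(direct_approach(g, "R2"), character())
  expect_error(direct_approach(g, "N1"), class = "raredr_config_error")
})

test_that("the six paths match hand enumeration on the fixture graph", {
  g <- toy_paths_graph()
  p <- paths_approach(g, "RD")
  expect_identical(p$per_path,
                   list(P1 = "DA", P2 = "DB", P3 = "DC", P4 = "DD",
                        P5 = "DE", P6 = "DF"))
  expect_identical(p$combined, character())
  expect_identical(p$per_path$P5, direct_approach(g, "RD"))
})

test_that("a single non-empty path set passes through the intersection", {
  g <- toy_triples_graph()
  # only P2/P4-style indication edges exist; paths through targets are empty
  p <- paths_approach(g, "R")
  nonempty <- Filter(length, p$per_path)
  expect_identical(p$combined, sort(Reduce(intersect, nonempty)))
})

test_that("cross-feature triples intersection keeps drugs shared across groups", {
  g <- toy_triples_graph()
  tri <- triples_approach(g, "R", k = 5, share_min = 1)
  expect_identical(tri$per_feature$gene, c("d1", "d2"))
  expect_identical(tri$per_feature$symptom, "d2")
  expect_identical(tri$combined, "d2")
  # share_min = 2 with single-neighbour groups: nothing shared
  expect_identical(triples_approach(g, "R", share_min = 2)$combined, character())
})

test_that("graphs without indication edges yield empty triples results", {
  g <- toy_direct_graph()
  tri <- triples_approach(g, "R1")
  expect_true(all(lengths(tri$per_feature) == 0))
  expect_identical(tri$combined, character())
})

test_that("the target constraint filters drugs without a shared target-encoding gene", {
  gen <- generate_graph(strong_config(61, planted_overlap = 1.0))
  g <- gen$graph
  pl <- gen$planted[1, ]
  tt <- triples_target_approach(g, pl$rare_disease_id)
  expect_true(pl$drug_id %in% tt$combined)

  # removing the rare disease's copy of the shared gene breaks the constraint
  edges <- g$edges
  drop <- edges$disease_gene$disease_id == pl$rare_disease_id &
    edges$disease_gene$feature_id == pl$shared_gene
  edges$disease_gene <- edges$disease_gene[!drop, ]
  g2 <- knowledge_graph(g$diseases, g$drugs, g$nodes, edges)
  tt2 <- triples_target_approach(g2, pl$rare_disease_id)
  expect_false(pl$drug_id %in% unlist(tt2$per_feature))

  # empty gene-protein map: no chain can be completed
  edges <- g$edges
  edges$gene_protein <- edges$gene_protein[0, ]
  edges$drug_target <- edges$drug_target[0, ]
  edges$gda <- edges$gda[0, ]
  g3 <- knowledge_graph(g$diseases, g$drugs, g$nodes, edges)
  expect_identical(triples_target_approach(g3, pl$rare_disease_id)$combined,
                   character())
})

test_that("combiner semantics: intersection over non-empty member sets", {
  big <- sprintf("D%04d", 1:965)
  res <- combine_approaches(list(triples = character(), triples_target = character(),
                                 direct = character(), paths = big))
  expect_identical(res$all, sort(big))
  expect_identical(res$ttddrp, sort(big))

  res <- combine_approaches(list(triples = c("a", "b"), triples_target = character(),
                                 direct = c("b", "c"), paths = "b"))
  expect_identical(res$all, "b")
  expect_identical(res$ttddrp, "b")

  res <- combine_approaches(list(triples = "a", triples_target = "b",
                                 direct = character(), paths = character()))
  expect_identical(res$all, character())
  expect_identical(res$ttddrp, "b")

  res <- combine_approaches(list(triples = character(), triples_target = character(),
                                 direct = character(), paths = character()))
  expect_identical(res$all, character())
  expect_identical(res$ttddrp, character())
})

test_that("every approach matches its brute-force oracle on random small graphs", {
  for (seed in 71:80) {
    gen <- generate_graph(tiny_config(seed, n_planted = seed %% 2))
    g <- gen$graph
    for (r in raredr:::rare_ids(g)) {
      expect_identical(direct_approach(g, r), oracle_direct(g, r))
      got <- suppressMessages(triples_approach(g, r))
      exp <- oracle_triples(g, r)
      expect_identical(got$per_feature, exp$per_feature)
      expect_identical(got$combined, exp$combined)
      gott <- suppressMessages(triples_target_approach(g, r))
      expt <- oracle_triples(g, r, constrain = TRUE)
      expect_identical(gott$combined, expt$combined)
      gp <- paths_approach(g, r)
      ep <- oracle_paths(g, r)
      expect_identical(gp$per_path, ep$per_path)
      expect_identical(gp$combined, ep$combined)
      expect_identical(gp$per_path$P5, direct_approach(g, r))
    }
  }
})

test_that("combined sets are subsets of every non-empty approach set", {
  for (seed in 81:86) {
    g <- generate_graph(tiny_config(seed, n_planted = 1))$graph
    run <- suppressMessages(run_all(g, raredr:::rare_ids(g)))
    for (res in run$results) {
      for (s in Filter(length, res$per_approach)) {
        expect_true(all(res$all_combined %in% s))
      }
      tt_members <- Filter(length, res$per_approach[c("triples_target", "direct", "paths")])
      for (s in tt_members) expect_true(all(res$ttddrp_combined %in% s))
      nonempty <- Filter(length, res$per_approach)
      if (length(nonempty) == 1) {
        expect_identical(res$all_combined, sort(nonempty[[1]]))
      }
    }
  }
})

test_that("summary counts equal the stored set cardinalities", {
  g <- generate_graph(tiny_config(87, n_planted = 1))$graph
  run <- suppressMessages(run_all(g, raredr:::rare_ids(g)))
  for (i in seq_len(nrow(run$summary))) {
    res <- run$results[[run$summary$rare_id[i]]]
    expect_identical(run$summary$direct[i], length(res$per_approach$direct))
    expect_identical(run$summary$all[i], length(res$all_combined))
    expect_identical(run$summary$ttddrp[i], length(res$ttddrp_combined))
  }
})

test_that("drugs already indicated for the disease are excluded as known treatments", {
  g <- toy_direct_graph()
  edges <- g$edges
  edges$drug_indication <- data.frame(drug_id = "D1", node_id = "R1")
  g2 <- knowledge_graph(g$diseases, g$drugs, g$nodes, edges)
  run <- run_all(g2, "R1")
  expect_identical(run$results$R1$known_treatments, "D1")
  expect_false("D1" %in% run$results$R1$per_approach$direct)
  run_keep <- run_all(g2, "R1", exclude_known = FALSE)
  expect_true("D1" %in% run_keep$results$R1$per_approach$direct)
})
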