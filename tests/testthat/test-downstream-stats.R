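test_that("validation bookkeeping totals and fractions are column arithmetic", {
  vs <- validation_summary(checked_drugs_fixture())
  total <- vs$table[vs$table$disease_id == "TOTAL", ]
  expect_identical(total$checked, 60L)
  expect_identical(total$toxic, 33L)
  expect_identical(total$therapeutic, 27L)
  expect_equal(vs$frac_with_therapeutic, 8 / 12)
  expect_equal(vs$frac_with_evidence, 11 / 12)
})

test_that("validation bookkeeping identities are enforced", {
  counts <- data.frame(disease_id = "X", computational = 5L, checked = 3L,
                       therapeutic = 1L, toxic = 1L)
  expect_error(validation_summary(counts), "therapeutic",
               class = "raredr_validation_error")
  counts <- data.frame(disease_id = "X", computational = 2L, checked = 3L,
                       therapeutic = 2L, toxic = 1L)
  expect_error(validation_summary(counts), "exceed",
               class = "raredr_validation_error")
  counts <- data.frame(disease_id = c("X", "X"), computational = 2L,
                       checked = 1L, therapeutic = 1L, toxic = 0L)
  expect_error(validation_summary(counts), class = "raredr_validation_error")
})

fake_result <- function(rare_id, ttddrp, all = ttddrp) {
  structure(list(rare_id = rare_id, ttddrp_combined = ttddrp,
                 all_combined = all), class = "approach_result")
}

test_that("per-drug records are tallied against the candidate sets", {
  results <- list(
    A = fake_result("A", c("d1", "d2", "d3")),
    B = fake_result("B", character(), all = "d9"))
  records <- data.frame(
    disease_id = c("A", "A", "A", "B"),
    drug_id = c("d1", "d2", "d3", "d9"),
    status = c("therapeutic", "toxic", "unverified", "toxic"))
  vs <- summarize_validation(records, results)
  a <- vs$table[vs$table$disease_id == "A", ]
  expect_identical(a$computational, 3L)
  expect_identical(a$checked, 2L)
  expect_identical(a$therapeutic, 1L)
  total <- vs$table[vs$table$disease_id == "TOTAL", ]
  expect_identical(total$checked, 3L)

  records$drug_id[1] <- "not_a_candidate"
  expect_error(summarize_validation(records, results), "non-candidate",
               class = "raredr_validation_error")
  expect_error(summarize_validation(
    data.frame(disease_id = "A", drug_id = "d1", status = "maybe"), results),
    class = "raredr_validation_error")
})

test_that("ATC level-1 composition counts multi-class drugs once per class", {
  g <- knowledge_graph(
    diseases = data.frame(id = "R1", name = "r", is_rare = TRUE,
                          prevalence_class = "unknown",
                          prevalence_geography = "Worldwide"),
    drugs = data.frame(id = c("dA", "dB", "dC"), name = "d",
                       atc_codes = c("C07AG02", "L01XE05;N02BA01", "")),
    nodes = data.frame(id = character(), role = character()))
  one <- atc_level1_composition("dA", g)
  expect_identical(one[["C"]], 1L)
  expect_identical(sum(one), 1L)
  multi <- atc_level1_composition(c("dA", "dB", "dC"), g)
  expect_identical(multi[["L"]], 1L)
  expect_identical(multi[["N"]], 1L)
  expect_identical(multi[["unclassified"]], 1L)
  expect_identical(sum(multi), 4L) # dB spans two classes
  expect_error(atc_level1_composition("ghost", g), class = "raredr_lookup_error")
})

test_that("Welch test agrees with independently computed reference values", {
  cases <- list(
    list(x = c(0.12, 0.25, 0.31, 0.45, 0.52),
         y = c(0.05, 0.07, 0.10, 0.15, 0.22, 0.30), p = 0.0645600583),
    list(x = c(1.2, 1.9, 2.3, 2.8), y = c(0.8, 1.1, 1.4), p = 0.0618469976),
    list(x = c(0.9, 1.0, 1.1, 1.4, 1.7, 2.0),
         y = c(0.6, 0.65, 0.7, 0.8, 1.2), p = 0.0266684350))
  for (cs in cases) {
    expect_equal(raredr:::welch_test(cs$x, cs$y)$p_value, cs$p, tolerance = 1e-8)
  }
})

# graph whose GDA table holds exactly the given hypothesis/background scores
gda_graph <- function(x, y) {
  gx <- sprintf("GX%02d", seq_along(x))
  gy <- sprintf("GY%02d", seq_along(y))
  knowledge_graph(
    diseases = data.frame(id = c("RH", "NB"), name = "d",
                          is_rare = c(TRUE, FALSE), prevalence_class = "unknown",
                          prevalence_geography = "Worldwide"),
    drugs = data.frame(id = character(), name = character(), atc_codes = character()),
    nodes = data.frame(id = c(gx, gy), role = "gene"),
    edges = list(
      disease_gene = data.frame(disease_id = rep(c("RH", "NB"), c(length(x), length(y))),
                                feature_id = c(gx, gy)),
      gda = data.frame(gene_id = c(gx, gy),
                       disease_id = rep(c("RH", "NB"), c(length(x), length(y))),
                       gda_score = c(x, y), dsi = 0.5, dpi = 0.5)))
}

test_that("Mann-Whitney test agrees with independently computed reference values", {
  cases <- list(
    list(x = c(0.12, 0.25, 0.31, 0.45, 0.52),
         y = c(0.05, 0.07, 0.10, 0.15, 0.22, 0.30), p = 0.0519480519),
    list(x = c(0.9, 1.0, 1.1, 1.4, 1.7, 2.0) / 3,
         y = c(0.6, 0.65, 0.7, 0.8, 1.2) / 3, p = 0.0303030303))
  for (cs in cases) {
    g <- gda_graph(cs$x, cs$y)
    pairs <- data.frame(rare_id = "RH", gene = sprintf("GX%02d", seq_along(cs$x)))
    res <- gda_test(g, pairs, leave_out = TRUE)
    expect_equal(res$p_value, cs$p, tolerance = 1e-8)
    expect_identical(res$direction, "expected")
  }
})

test_that("degenerate all-tied GDA scores give p = 1; reversed signals are flagged", {
  g <- gda_graph(c(0.5, 0.5), rep(0.5, 8))
  pairs <- data.frame(rare_id = "RH", gene = c("GX01", "GX02"))
  res <- gda_test(g, pairs)
  expect_identical(res$p_value, 1)

  g <- gda_graph(c(0.01, 0.02, 0.03), c(0.7, 0.8, 0.85, 0.9, 0.95, 0.99))
  res <- gda_test(g, pairs = data.frame(rare_id = "RH",
                                        gene = c("GX01", "GX02", "GX03")),
                  leave_out = TRUE)
  expect_identical(res$direction, "reversed")
  expect_lt(res$p_value, 0.05)

  expect_error(gda_test(g, data.frame(rare_id = "RH", gene = "GY01")),
               class = "raredr_validation_error")
})

# rare disease R1 and non-rare N1 with identical symptom sets sharing a
# drug-targeted gene; N2 shares nothing
ps_graph <- function() {
  knowledge_graph(
    diseases = data.frame(id = c("R1", "N1", "N2"), name = "d",
                          is_rare = c(TRUE, FALSE, FALSE),
                          prevalence_class = "unknown",
                          prevalence_geography = "Worldwide"),
    drugs = data.frame(id = "D1", name = "d", atc_codes = ""),
    nodes = data.frame(id = c("G1", "P1", "S1", "S2", "S3"),
                       role = c("gene", "protein", "symptom", "symptom", "symptom")),
    edges = list(
      disease_gene = data.frame(disease_id = c("R1", "N1"), feature_id = "G1"),
      disease_symptom = data.frame(
        disease_id = c("R1", "R1", "N1", "N1", "N2"),
        feature_id = c("S1", "S2", "S1", "S2", "S3")),
      gene_protein = data.frame(gene_id = "G1", protein_id = "P1"),
      drug_target = data.frame(drug_id = "D1", node_id = "P1")))
}

test_that("identical hypothesis diseases give mean similarity 1", {
  g <- ps_graph()
  res <- phenotypic_similarity_test(g, data.frame(rare_id = "R1", nonrare_id = "N1"))
  expect_identical(res$mean_hypothesis, 1)
  expect_identical(res$n_background, 2L)
  expect_identical(res$direction, "hypothesis_higher")
})

test_that("hypothesis pairs without a shared target-encoding gene are rejected", {
  g <- ps_graph()
  expect_error(
    phenotypic_similarity_test(g, data.frame(rare_id = "R1", nonrare_id = "N2")),
    "N2", class = "raredr_validation_error")
  expect_error(phenotypic_similarity_test(g, data.frame()),
               class = "raredr_config_error")
})

test_that("the Welch stage detects strong planted phenotypic signal", {
  gen <- generate_graph(strong_config(91, planted_overlap = 1.0))
  pl <- gen$planted[1, ]
  confs <- strsplit(pl$confederate_ids, ";")[[1]]
  pairs <- data.frame(rare_id = pl$rare_disease_id, nonrare_id = confs,
                      drug_id = pl$drug_id)
  res <- phenotypic_similarity_test(gen$graph, pairs)
  expect_gt(res$mean_hypothesis, res$mean_background)
  expect_lt(res$p_value, 0.05)
})
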