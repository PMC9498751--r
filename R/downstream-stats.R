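# Validation-side analytics: literature-validation bookkeeping, ATC level-1
# composition, the Welch phenotypic-similarity test, and the Mann-Whitney
# gene-disease association test, plus the calibration simulations used to
# check both tests.

#' Build and check a validation summary from per-disease counts
#'
#' Enforces the bookkeeping identities of a literature-validation table --
#' per disease, `checked = therapeutic + toxic` (unverified candidates are
#' computational but not checked) and `checked <= computational` -- and
#' appends a totals row. Also reports two success fractions: diseases with at
#' least one therapeutic drug, and diseases with any literature evidence.
#'
#' @param counts Data frame with columns `disease_id`, `computational`,
#'   `checked`, `therapeutic`, `toxic` (one row per disease).
#' @return List with `table` (the counts plus a `TOTAL` row),
#'   `frac_with_therapeutic`, and `frac_with_evidence`.
#' @export
validation_summary <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("disease_id", "computational", "checked", "therapeutic", "toxic")
  missing <- setdiff(need, names(counts))
  if (length(missing)) abort_validation(sprintf("missing column '%s'", missing[1]))
  if (anyDuplicated(counts$disease_id)) {
    abort_validation("each disease may appear at most once")
  }
  bad <- counts$checked != counts$therapeutic + counts$toxic
  if (any(bad)) {
    abort_validation(sprintf(
      "checked != therapeutic + toxic for disease '%s'", counts$disease_id[bad][1]))
  }
  if (any(counts$checked > counts$computational)) {
    abort_validation("checked cannot exceed computational candidates")
  }
  totals <- tibble::tibble(
    disease_id = "TOTAL",
    computational = sum(counts$computational),
    checked = sum(counts$checked),
    therapeutic = sum(counts$therapeutic),
    toxic = sum(counts$toxic))
  keep <- c("disease_id", intersect("disease", names(counts)),
            "computational", "checked", "therapeutic", "toxic")
  list(
    table = dplyr::bind_rows(counts[, intersect(keep, names(counts))], totals),
    frac_with_therapeutic = mean(counts$therapeutic > 0),
    frac_with_evidence = mean(counts$checked > 0)
  )
}

#' Summarise per-drug validation records against candidate sets
#'
#' Turns per-drug literature verdicts (`therapeutic`, `toxic`, `unverified`)
#' into the per-disease count table checked by [validation_summary()]. The
#' computational candidate set of a disease is its `ttddrp_combined` set when
#' non-empty, otherwise its `all_combined` set. A record naming a drug that
#' is not among the disease's candidates is a validation error.
#'
#' @param records Data frame with columns `disease_id`, `drug_id`, `status`
#'   (one of therapeutic/toxic/unverified), optional `evidence`.
#' @param results The `results` element of [run_all()].
#' @return As [validation_summary()].
#' @export
summarize_validation <- function(records, results) {
  records <- tibble::as_tibble(records)
  bad_status <- setdiff(unique(records$status), c("therapeutic", "toxic", "unverified"))
  if (length(bad_status)) {
    abort_validation(sprintf("unknown validation status '%s'", bad_status[1]))
  }
  if (anyDuplicated(records[, c("disease_id", "drug_id")])) {
    abort_validation("a (disease, drug) pair appears more than once")
  }
  candidate_set <- function(res) {
    if (length(res$ttddrp_combined)) res$ttddrp_combined else res$all_combined
  }
  counts <- dplyr::bind_rows(lapply(results, function(res) {
    cand <- candidate_set(res)
    rec <- records[records$disease_id == res$rare_id, ]
    stray <- setdiff(rec$drug_id, cand)
    if (length(stray)) {
      abort_validation(sprintf(
        "validation record for '%s' names non-candidate drug '%s'",
        res$rare_id, stray[1]))
    }
    tibble::tibble(
      disease_id = res$rare_id,
      computational = length(cand),
      checked = sum(rec$status %in% c("therapeutic", "toxic")),
      therapeutic = sum(rec$status == "therapeutic"),
      toxic = sum(rec$status == "toxic"))
  }))
  validation_summary(counts)
}

#' ATC level-1 composition of a drug set
#'
#' Counts drugs per first-level (anatomical/pharmacological) ATC class. A
#' drug whose codes span several distinct first-level classes contributes one
#' count to each; a drug with no ATC code is counted as `unclassified`.
#'
#' @param drug_ids Drug identifiers, all declared in `g`.
#' @param g A `knowledge_graph`.
#' @return Named integer vector over the 14 ATC classes plus `unclassified`.
#' @export
atc_level1_composition <- function(drug_ids, g) {
  drug_ids <- unique(drug_ids)
  stray <- setdiff(drug_ids, g$drugs$id)
  if (length(stray)) abort_lookup(sprintf("unknown drug '%s'", stray[1]))
  codes <- split_atc(g$drugs$atc_codes[match(drug_ids, g$drugs$id)])
  classes <- c(atc_level1_letters(), "unclassified")
  out <- stats::setNames(integer(length(classes)), classes)
  for (cs in codes) {
    if (length(cs) == 0) {
      out["unclassified"] <- out["unclassified"] + 1L
    } else {
      for (lv1 in unique(substr(cs, 1, 1))) out[lv1] <- out[lv1] + 1L
    }
  }
  out
}

# Does a disease pair share a gene encoding a drug-target protein? When
# drug_id is given, the protein must be a target of that drug; otherwise any
# drug-targeted protein qualifies.
shares_target_gene <- function(g, rare_id, nonrare_id, drug_id = NULL) {
  dg <- g$edges$disease_gene
  shared <- intersect(dg$feature_id[dg$disease_id == rare_id],
                      dg$feature_id[dg$disease_id == nonrare_id])
  if (length(shared) == 0) return(FALSE)
  prots <- encoded_proteins(g, shared)
  e <- g$edges$drug_target
  targets <- if (is.null(drug_id)) e$node_id else e$node_id[e$drug_id == drug_id]
  length(intersect(prots, targets)) > 0
}

# Welch two-sample t test wrapper shared by the phenotypic-similarity stage
# and its null-calibration simulation.
welch_test <- function(x, y) {
  # p is undefined for singleton or fully constant samples; report NA rather
  # than erroring so tiny hypothesis sets still yield their group means
  p <- if (length(x) >= 2 && length(y) >= 2 && (stats::sd(x) > 0 || stats::sd(y) > 0)) {
    unname(stats::t.test(x, y, var.equal = FALSE)$p.value)
  } else NA_real_
  list(p_value = p, mean_x = mean(x), mean_y = mean(y),
       direction = if (mean(x) >= mean(y)) "hypothesis_higher" else "reversed")
}

#' Phenotypic-similarity test of repurposing-hypothesis pairs
#'
#' Compares symptom-based Jaccard similarity of the hypothesis disease pairs
#' (each pair must share a gene encoding a drug-target protein; violating
#' pairs raise a validation error) against the background of all rare/non-rare
#' pairs in the graph, using a two-sided Welch t test (unequal variances).
#' Direction is reported separately so reversed findings stay visible.
#'
#' @param g A `knowledge_graph`.
#' @param hypothesis_pairs Data frame with columns `rare_id`, `nonrare_id`,
#'   optional `drug_id` (tightens the shared-gene check to that drug's
#'   targets).
#' @param feature Feature kind to compare on (default `"symptom"`).
#' @return List with `mean_hypothesis`, `mean_background`, `p_value`,
#'   `direction`, `n_hypothesis`, `n_background`.
#' @export
phenotypic_similarity_test <- function(g, hypothesis_pairs, feature = "symptom") {
  hypothesis_pairs <- tibble::as_tibble(hypothesis_pairs)
  if (nrow(hypothesis_pairs) == 0) abort_config("hypothesis_pairs must be non-empty")
  has_drug <- "drug_id" %in% names(hypothesis_pairs)
  ok <- vapply(seq_len(nrow(hypothesis_pairs)), function(i) {
    shares_target_gene(g, hypothesis_pairs$rare_id[i], hypothesis_pairs$nonrare_id[i],
                       if (has_drug) hypothesis_pairs$drug_id[i] else NULL)
  }, logical(1))
  if (any(!ok)) {
    bad <- hypothesis_pairs[!ok, ]
    abort_validation(sprintf(
      "hypothesis pair(s) violate the shared-target-gene condition: %s",
      paste(sprintf("(%s, %s)", bad$rare_id, bad$nonrare_id), collapse = ", ")))
  }
  prof <- profiles_by_feature(g, feature)
  hyp <- vapply(seq_len(nrow(hypothesis_pairs)), function(i) {
    jaccard(prof[[hypothesis_pairs$rare_id[i]]], prof[[hypothesis_pairs$nonrare_id[i]]])
  }, numeric(1))
  bg <- all_pair_similarities(g, rare_ids(g), feature)$score
  ht <- welch_test(hyp, bg)
  list(mean_hypothesis = ht$mean_x, mean_background = ht$mean_y,
       p_value = ht$p_value, direction = ht$direction,
       n_hypothesis = length(hyp), n_background = length(bg))
}

#' Gene-disease association test per rare disease
#'
#' For each rare disease in `pairs`, compares the GDA scores of its
#' hypothesis (rare disease, target gene) pairs against the background of all
#' GDA scores in the graph using a two-sided Mann-Whitney U test. Pairs with
#' no GDA record raise a validation error. The background includes the
#' hypothesis records unless `leave_out = TRUE`.
#'
#' @param g A `knowledge_graph`.
#' @param pairs Data frame with columns `rare_id`, `gene`.
#' @param leave_out Exclude the hypothesis records from the background.
#' @return Tibble with one row per rare disease: `rare_id`, `n_hypothesis`,
#'   `n_background`, `median_hypothesis`, `median_background`, `p_value`,
#'   `direction` (`"expected"` when hypothesis scores run higher,
#'   `"reversed"` otherwise).
#' @export
gda_test <- function(g, pairs, leave_out = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  gda <- g$edges$gda
  key <- paste(gda$disease_id, gda$gene_id)
  pk <- paste(pairs$rare_id, pairs$gene)
  missing <- !(pk %in% key)
  if (any(missing)) {
    abort_validation(sprintf("no GDA record for pair (%s, %s)",
                             pairs$rare_id[missing][1], pairs$gene[missing][1]))
  }
  dplyr::bind_rows(lapply(split(pairs, pairs$rare_id), function(pr) {
    idx <- key %in% paste(pr$rare_id, pr$gene)
    x <- gda$gda_score[idx]
    y <- if (leave_out) gda$gda_score[!idx] else gda$gda_score
    p <- if (length(unique(c(x, y))) == 1) {
      1 # no separation at all: every observation tied
    } else {
      unname(suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value)
    }
    tibble::tibble(
      rare_id = pr$rare_id[1],
      n_hypothesis = length(x),
      n_background = length(y),
      median_hypothesis = stats::median(x),
      median_background = stats::median(y),
      p_value = p,
      direction = if (stats::median(x) >= stats::median(y)) "expected" else "reversed")
  }))
}

#' Type-I-error calibration of the Welch phenotypic-similarity test
#'
#' Simulates the null: both "hypothesis" and "background" samples are drawn
#' (with replacement, independently) from the empirical pool of background
#' similarity scores of `g`, and the Welch test of the phenotypic-similarity
#' stage is applied. Returns the rejection rate at `alpha`, which should sit
#' near `alpha` when the test is calibrated for these score distributions.
#'
#' @param g A `knowledge_graph` providing the empirical score pool.
#' @param n_reps Number of simulated null datasets.
#' @param n_hyp,n_bg Sample sizes per replicate.
#' @param alpha Nominal level.
#' @param seed Seed for the simulation.
#' @param feature Feature kind for the score pool.
#' @return List with `rejection_rate`, `n_reps`, `alpha`.
#' @export
simulate_welch_null <- function(g, n_reps = 1000, n_hyp = 100, n_bg = 400,
                                alpha = 0.05, seed = 1L, feature = "symptom") {
  pool <- all_pair_similarities(g, rare_ids(g), feature)$score
  if (length(unique(pool)) < 2) {
    abort_config("background score pool is degenerate; increase overlap or graph size")
  }
  rej <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      x <- sample(pool, n_hyp, replace = TRUE)
      y <- sample(pool, n_bg, replace = TRUE)
      if (stats::sd(x) == 0 && stats::sd(y) == 0) return(FALSE)
      welch_test(x, y)$p_value < alpha
    }, logical(1))
  })
  list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
}

#' Power of the Mann-Whitney GDA test under planted signal
#'
#' Repeatedly generates a synthetic graph with planted hypotheses (high-Beta
#' GDA scores for planted rare diseases, low-Beta background), runs
#' [gda_test()] on each planted disease's gene associations, and reports the
#' fraction of planted diseases detected (two-sided p below `alpha` with the
#' expected direction).
#'
#' @param config A [generator_config()] with `n_planted > 0`.
#' @param n_reps Number of generated graphs.
#' @param alpha Nominal level.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `power`, `n_tests`, `alpha`.
#' @export
simulate_gda_power <- function(config = generator_config(n_rare = 6, n_nonrare = 60,
                                                         n_drugs = 25, n_planted = 3),
                               n_reps = 20, alpha = 0.05, seed = 1L) {
  if (config$n_planted < 1) abort_config("config must plant at least one hypothesis")
  hits <- integer(0)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer((seed + r) %% 2147483647)
    gen <- generate_graph(cfg)
    dg <- gen$graph$edges$disease_gene
    for (rid in gen$planted$rare_disease_id) {
      pairs <- tibble::tibble(rare_id = rid,
                              gene = dg$feature_id[dg$disease_id == rid])
      res <- gda_test(gen$graph, pairs)
      hits <- c(hits, as.integer(res$p_value < alpha && res$direction == "expected"))
    }
  }
  list(power = mean(hits), n_tests = length(hits), alpha = alpha)
}
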