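# End-to-end orchestration: select -> similarity -> reposition -> stats,
# writing a deterministic TSV report bundle plus a manifest.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run in one serialisable object. The
#' graph is either loaded from `graph_dir` or generated from `generator`
#' (exactly one must be given).
#'
#' @param graph_dir Directory holding a saved graph file set, or `NULL`.
#' @param generator A [generator_config()], or `NULL`.
#' @param criteria A [selection_criteria()].
#' @param k,share_min,restrict_nonrare,exclude_known Repositioning
#'   parameters, see [run_all()].
#' @param feature Feature kind for the phenotypic-similarity test.
#' @param alpha Nominal level reported alongside the tests.
#' @param validation Optional data frame of per-drug validation records
#'   (see [summarize_validation()]).
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(graph_dir = NULL, generator = NULL,
                            criteria = selection_criteria(
                              geography_whitelist = NULL,
                              prevalence_whitelist = NULL),
                            k = 5, share_min = 2, restrict_nonrare = TRUE,
                            exclude_known = TRUE, feature = "symptom",
                            alpha = 0.05, validation = NULL, seed = 1L) {
  if (is.null(graph_dir) == is.null(generator)) {
    abort_config("exactly one of graph_dir or generator must be given")
  }
  structure(list(graph_dir = graph_dir, generator = generator,
                 criteria = criteria, k = k, share_min = share_min,
                 restrict_nonrare = restrict_nonrare,
                 exclude_known = exclude_known, feature = feature,
                 alpha = alpha, validation = validation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Serialisable echo of a config with no filesystem paths, so two runs of the
# same analysis written to different places produce identical bundles.
config_echo <- function(config) {
  cr <- unclass(config$criteria)
  list(
    seed = config$seed,
    k = config$k, share_min = config$share_min,
    restrict_nonrare = config$restrict_nonrare,
    exclude_known = config$exclude_known,
    feature = config$feature, alpha = config$alpha,
    criteria = lapply(cr, function(v) if (is.null(v)) "disabled" else v),
    generator = if (!is.null(config$generator)) {
      lapply(unclass(config$generator), function(v) as.vector(v))
    } else "external graph"
  )
}

#' Run the full repositioning pipeline
#'
#' Loads or generates the knowledge graph, selects the study diseases, ranks
#' similarities, runs the four candidate-generation approaches, and computes
#' the downstream statistics, writing a report bundle to `out_dir`:
#' `selected.tsv` and `attrition.tsv`, `sim_<feature>.tsv` per feature kind,
#' `summary.tsv` (per-approach and combined candidate counts),
#' `candidates.tsv` (per-disease drug memberships), `ps_test.tsv`,
#' `gda_test.tsv`, `atc_histogram.tsv`, optionally
#' `validation_summary.tsv`, plus `config.yaml` and `manifest.yaml` (package
#' version, seed, md5 digests of inputs and outputs). Identical configuration
#' and seed produce a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage outputs (`graph`,
#'   `selection`, `repositioning`, `ps_test`, `gda_test`, `atc`, `files`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("config must be built with pipeline_config()")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(label, expr) {
    withCallingHandlers(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", label,
                           conditionMessage(e)), parent = e)
    })
  }

  graph <- stage("load_graph", {
    if (!is.null(config$graph_dir)) {
      if (!dir.exists(config$graph_dir)) {
        abort_config(sprintf("graph directory '%s' does not exist", config$graph_dir))
      }
      load_graph(config$graph_dir)
    } else {
      generate_graph(config$generator)$graph
    }
  })
  input_digests <- if (!is.null(config$graph_dir)) {
    files <- file.path(config$graph_dir, graph_files())
    stats::setNames(unname(tools::md5sum(files)), basename(files))
  } else {
    list(generated_from = "generator config", seed = config$generator$seed)
  }

  paths <- list()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    paths[[name]] <<- p
  }

  sel <- stage("select", select_diseases(graph, config$criteria))
  wr(tibble::tibble(disease_id = sel$ids), "selected.tsv")
  wr(sel$attrition, "attrition.tsv")

  stage("similarity", for (feat in feature_kinds()) {
    sims <- if (length(sel$ids)) {
      s <- all_pair_similarities(graph, sel$ids, feat)
      s <- s[s$score > 0, ]
      s <- s[order(s$rare_id, -s$score, s$nonrare_id), ]
      s$rank <- stats::ave(seq_len(nrow(s)), s$rare_id, FUN = seq_along)
      s
    } else {
      tibble::tibble(rare_id = character(), nonrare_id = character(),
                     feature = character(), score = double(), rank = integer())
    }
    wr(sims, sprintf("sim_%s.tsv", feat))
  })

  repo <- stage("reposition", run_all(
    graph, sel$ids, k = config$k, share_min = config$share_min,
    restrict_nonrare = config$restrict_nonrare,
    exclude_known = config$exclude_known))
  wr(repo$summary, "summary.tsv")
  cand_rows <- lapply(repo$results, function(res) {
    drugs <- set_sorted(unlist(res$per_approach))
    if (length(drugs) == 0) return(NULL)
    tibble::tibble(
      disease_id = res$rare_id, drug_id = drugs,
      approaches = vapply(drugs, function(d) {
        paste(names(res$per_approach)[vapply(res$per_approach, function(s) d %in% s,
                                             logical(1))], collapse = ";")
      }, ""),
      in_all = drugs %in% res$all_combined,
      in_ttddrp = drugs %in% res$ttddrp_combined)
  })
  wr(dplyr::bind_rows(cand_rows), "candidates.tsv")

  candidate_union <- set_sorted(unlist(lapply(repo$results, function(res) {
    if (length(res$ttddrp_combined)) res$ttddrp_combined else res$all_combined
  })))

  hyp <- stage("stats", derive_hypothesis_pairs(graph, repo$results))
  ps <- NULL
  if (nrow(hyp)) {
    ps <- phenotypic_similarity_test(graph, hyp, feature = config$feature)
    wr(tibble::tibble(mean_hypothesis = ps$mean_hypothesis,
                      mean_background = ps$mean_background,
                      p_value = ps$p_value, direction = ps$direction,
                      n_hypothesis = ps$n_hypothesis,
                      n_background = ps$n_background), "ps_test.tsv")
  } else {
    wr(tibble::tibble(mean_hypothesis = double(), mean_background = double(),
                      p_value = double(), direction = character(),
                      n_hypothesis = integer(), n_background = integer()),
       "ps_test.tsv")
  }

  gda_pairs <- derive_gda_pairs(graph, repo$results)
  gda <- if (nrow(gda_pairs)) gda_test(graph, gda_pairs) else
    tibble::tibble(rare_id = character(), n_hypothesis = integer(),
                   n_background = integer(), median_hypothesis = double(),
                   median_background = double(), p_value = double(),
                   direction = character())
  wr(gda, "gda_test.tsv")

  atc <- atc_level1_composition(candidate_union, graph)
  wr(tibble::tibble(atc_class = names(atc), n_drugs = as.integer(atc)),
     "atc_histogram.tsv")

  if (!is.null(config$validation)) {
    vs <- summarize_validation(config$validation, repo$results)
    wr(vs$table, "validation_summary.tsv")
  }

  yaml::write_yaml(config_echo(config), file.path(out_dir, "config.yaml"))
  paths[["config.yaml"]] <- file.path(out_dir, "config.yaml")
  manifest <- list(
    package = "raredr",
    version = as.character(utils::packageVersion("raredr")),
    seed = config$seed,
    inputs = as.list(input_digests),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(unlist(paths))), names(paths)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(graph = graph, selection = sel, repositioning = repo,
                 ps_test = ps, gda_test = gda, atc = atc,
                 files = c(unlist(paths), file.path(out_dir, "manifest.yaml"))))
}

#' Derive phenotypic-similarity hypothesis pairs from repositioning results
#'
#' For each study disease and each of its combined candidate drugs (the
#' target-constrained combination when non-empty, otherwise the
#' all-approaches combination), pairs the rare disease with every non-rare
#' disease for which the drug is indicated, keeping pairs that share a gene
#' encoding a target of that drug.
#'
#' @param g A `knowledge_graph`.
#' @param results The `results` element of [run_all()].
#' @return Tibble with columns `rare_id`, `nonrare_id`, `drug_id`.
#' @export
derive_hypothesis_pairs <- function(g, results) {
  e <- g$edges$drug_indication
  nr <- nonrare_ids(g)
  rows <- lapply(results, function(res) {
    cand <- if (length(res$ttddrp_combined)) res$ttddrp_combined else res$all_combined
    out <- list()
    for (d in cand) {
      partners <- intersect(unique(e$node_id[e$drug_id == d]), nr)
      keep <- partners[vapply(partners, function(n) {
        shares_target_gene(g, res$rare_id, n, d)
      }, logical(1))]
      if (length(keep)) {
        out[[d]] <- tibble::tibble(rare_id = res$rare_id, nonrare_id = keep,
                                   drug_id = d)
      }
    }
    dplyr::bind_rows(out)
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Derive gene-disease association hypothesis pairs
#'
#' For each study disease, collects its genes that encode a target protein of
#' one of its combined candidate drugs and that carry a GDA record, yielding
#' the (rare disease, gene) hypothesis pairs for [gda_test()].
#'
#' @inheritParams derive_hypothesis_pairs
#' @return Tibble with columns `rare_id`, `gene`.
#' @export
derive_gda_pairs <- function(g, results) {
  dg <- g$edges$disease_gene
  gp <- g$edges$gene_protein
  tgt <- g$edges$drug_target
  gda_key <- paste(g$edges$gda$disease_id, g$edges$gda$gene_id)
  rows <- lapply(results, function(res) {
    cand <- if (length(res$ttddrp_combined)) res$ttddrp_combined else res$all_combined
    if (length(cand) == 0) return(NULL)
    prots <- unique(tgt$node_id[tgt$drug_id %in% cand])
    genes <- unique(gp$gene_id[gp$protein_id %in% prots])
    genes <- intersect(genes, dg$feature_id[dg$disease_id == res$rare_id])
    genes <- genes[paste(res$rare_id, genes) %in% gda_key]
    if (length(genes) == 0) return(NULL)
    tibble::tibble(rare_id = res$rare_id, gene = sort(genes))
  })
  dplyr::bind_rows(rows)
}
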