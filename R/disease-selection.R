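# Disease-selection workflow: filter a disease universe down to the study set,
# with a per-stage attrition report.

#' Selection criteria for the study disease set
#'
#' The filters mirror a four-criterion selection workflow: rarity, presence
#' of any graph annotation, absence of an existing treatment (no drug
#' indication edge pointing at the disease), availability of both gene and
#' symptom information, geographic scope of the prevalence estimate, the
#' prevalence class itself, and optional ceilings on profile sizes (a
#' computational-cost guard with no default value).
#'
#' @param require_rare Keep only diseases flagged rare.
#' @param require_in_graph Keep only diseases with at least one feature edge
#'   of any kind.
#' @param exclude_with_treatment Drop diseases that already have a drug
#'   indication edge.
#' @param require_genes_and_symptoms Keep only diseases with at least one
#'   gene and at least one symptom.
#' @param geography_whitelist Allowed prevalence-geography labels, or `NULL`
#'   to disable. Default `"Worldwide"`.
#' @param prevalence_whitelist Allowed prevalence classes, or `NULL` to
#'   disable. Default `"<1/1000000"`.
#' @param max_genes,max_symptoms Optional profile-size ceilings (`NULL`
#'   disables).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(require_rare = TRUE,
                               require_in_graph = TRUE,
                               exclude_with_treatment = TRUE,
                               require_genes_and_symptoms = TRUE,
                               geography_whitelist = "Worldwide",
                               prevalence_whitelist = "<1/1000000",
                               max_genes = NULL,
                               max_symptoms = NULL) {
  cr <- list(require_rare = isTRUE(require_rare),
             require_in_graph = isTRUE(require_in_graph),
             exclude_with_treatment = isTRUE(exclude_with_treatment),
             require_genes_and_symptoms = isTRUE(require_genes_and_symptoms),
             geography_whitelist = geography_whitelist,
             prevalence_whitelist = prevalence_whitelist,
             max_genes = max_genes, max_symptoms = max_symptoms)
  enabled <- cr$require_rare || cr$require_in_graph || cr$exclude_with_treatment ||
    cr$require_genes_and_symptoms || !is.null(geography_whitelist) ||
    !is.null(prevalence_whitelist) || !is.null(max_genes) || !is.null(max_symptoms)
  if (!enabled) abort_config("at least one selection criterion must be enabled")
  bad <- setdiff(prevalence_whitelist %||% character(), prevalence_classes())
  if (length(bad)) abort_config(sprintf("unknown prevalence class '%s'", bad[1]))
  structure(cr, class = "selection_criteria")
}

#' Select study diseases and report per-stage attrition
#'
#' Applies every enabled criterion in a fixed order (rare, in graph, no
#' treatment, genes and symptoms present, geography, prevalence class,
#' profile-size ceilings) and reports how many diseases survive each stage.
#' The surviving set is order-independent (filters commute); only the
#' attrition report depends on the stage order.
#'
#' @param g A `knowledge_graph`.
#' @param criteria A [selection_criteria()].
#' @return List with `ids` (sorted surviving disease ids) and `attrition`
#'   (tibble: `stage`, `surviving`). An empty result logs a warning but is
#'   not an error.
#' @export
select_diseases <- function(g, criteria = selection_criteria()) {
  if (!inherits(criteria, "selection_criteria")) {
    abort_config("criteria must be built with selection_criteria()")
  }
  d <- g$diseases
  gene_ct <- table(g$edges$disease_gene$disease_id)
  sym_ct <- table(g$edges$disease_symptom$disease_id)
  n_genes <- as.integer(gene_ct[d$id]); n_genes[is.na(n_genes)] <- 0L
  n_syms <- as.integer(sym_ct[d$id]); n_syms[is.na(n_syms)] <- 0L
  any_edge <- n_genes + n_syms
  for (feat in c("protein", "pathway", "variant")) {
    ct <- table(g$edges[[paste0("disease_", feat)]]$disease_id)
    v <- as.integer(ct[d$id]); v[is.na(v)] <- 0L
    any_edge <- any_edge + v
  }
  treated <- d$id %in% g$edges$drug_indication$node_id

  alive <- rep(TRUE, nrow(d))
  stages <- list(stage = "universe", surviving = nrow(d))
  report <- tibble::tibble(stage = "universe", surviving = nrow(d))
  add <- function(stage, keep) {
    alive <<- alive & keep
    report <<- dplyr::bind_rows(report,
      tibble::tibble(stage = stage, surviving = sum(alive)))
  }
  if (criteria$require_rare) add("rare", d$is_rare)
  if (criteria$require_in_graph) add("in_graph", any_edge > 0)
  if (criteria$exclude_with_treatment) add("no_treatment", !treated)
  if (criteria$require_genes_and_symptoms) {
    add("has_genes_and_symptoms", n_genes > 0 & n_syms > 0)
  }
  if (!is.null(criteria$geography_whitelist)) {
    add("geography", d$prevalence_geography %in% criteria$geography_whitelist)
  }
  if (!is.null(criteria$prevalence_whitelist)) {
    add("prevalence", d$prevalence_class %in% criteria$prevalence_whitelist)
  }
  if (!is.null(criteria$max_genes)) add("max_genes", n_genes <= criteria$max_genes)
  if (!is.null(criteria$max_symptoms)) add("max_symptoms", n_syms <= criteria$max_symptoms)

  ids <- sort(d$id[alive])
  if (length(ids) == 0) rlang::warn("disease selection returned an empty set")
  list(ids = ids, attrition = report)
}
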