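# The four candidate-generation approaches and their set-intersection
# combiners. All drug sets are returned as sorted character vectors so output
# is deterministic.

# Intersection over the non-empty member sets; empty when all members empty.
intersect_nonempty <- function(sets) {
  sets <- Filter(length, sets)
  if (length(sets) == 0) return(character())
  set_sorted(Reduce(intersect, sets))
}

assert_rare <- function(g, rare_id) {
  if (!rare_id %in% g$diseases$id) {
    abort_lookup(sprintf("unknown disease '%s'", rare_id))
  }
  if (!g$diseases$is_rare[match(rare_id, g$diseases$id)]) {
    abort_config(sprintf("'%s' is not flagged rare", rare_id))
  }
}

# Drugs of one neighbour that satisfy the shared-target-gene constraint:
# some gene associated with both diseases encodes a protein the drug targets.
target_constrained_drugs <- function(g, rare_id, neighbor_id, tmap) {
  shared_genes <- intersect(
    g$edges$disease_gene$feature_id[g$edges$disease_gene$disease_id == rare_id],
    g$edges$disease_gene$feature_id[g$edges$disease_gene$disease_id == neighbor_id])
  if (length(shared_genes) == 0) return(character())
  shared_prots <- encoded_proteins(g, shared_genes)
  cand <- drugs_indicated_for(g, neighbor_id)
  cand[vapply(cand, function(d) length(intersect(tmap[[d]], shared_prots)) > 0,
              logical(1))]
}

triples_engine <- function(g, rare_id, k, share_min, constrain_target) {
  tmap <- if (constrain_target) drug_target_map(g) else NULL
  per_feature <- lapply(stats::setNames(feature_kinds(), feature_kinds()),
                        function(feat) {
    top <- rank_neighbors(g, rare_id, feat, k = k)
    if (nrow(top) == 0) return(character())
    tallies <- table(unlist(lapply(top$nonrare_id, function(n) {
      if (constrain_target) target_constrained_drugs(g, rare_id, n, tmap)
      else drugs_indicated_for(g, n)
    })))
    set_sorted(names(tallies)[tallies >= share_min])
  })
  list(per_feature = per_feature, combined = intersect_nonempty(per_feature))
}

#' Triples approach: shared drugs of the top-k similar diseases
#'
#' For each of the five feature kinds, takes the top-k non-rare diseases most
#' similar to the rare disease, collects the drugs indicated for those
#' neighbours, and keeps drugs linked to at least `share_min` of them; the
#' final candidate set is the intersection of the non-empty per-feature drug
#' groups (empty groups are excluded from the intersection).
#'
#' @param g A `knowledge_graph`.
#' @param rare_id A rare disease in `g`.
#' @param k Neighbours per feature ranking (default 5).
#' @param share_min Minimum number of top-k neighbours a drug must be linked
#'   to (default 2; set to `k` for a strict-intersection reading).
#' @return List with `per_feature` (named list of drug sets) and `combined`.
#' @export
triples_approach <- function(g, rare_id, k = 5, share_min = 2) {
  assert_rare(g, rare_id)
  triples_engine(g, rare_id, k, share_min, constrain_target = FALSE)
}

#' Target-constrained triples approach
#'
#' Identical to [triples_approach()] except that a candidate drug only counts
#' towards a neighbour when the rare disease and that neighbour share a gene
#' that encodes a protein target of the drug.
#'
#' @inheritParams triples_approach
#' @return List with `per_feature` (named list of drug sets) and `combined`.
#' @export
triples_target_approach <- function(g, rare_id, k = 5, share_min = 2) {
  assert_rare(g, rare_id)
  triples_engine(g, rare_id, k, share_min, constrain_target = TRUE)
}

#' Direct approach: drugs targeting proteins encoded by the disease's genes
#'
#' A drug is a candidate when some gene associated with the rare disease
#' encodes a protein that the drug targets.
#'
#' @inheritParams triples_approach
#' @return Sorted character vector of drug ids.
#' @export
direct_approach <- function(g, rare_id) {
  assert_rare(g, rare_id)
  genes <- g$edges$disease_gene$feature_id[g$edges$disease_gene$disease_id == rare_id]
  prots <- encoded_proteins(g, genes)
  e <- g$edges$drug_target
  set_sorted(e$drug_id[e$node_id %in% prots])
}

#' Paths approach: six traversal strategies and their intersection
#'
#' Computes six drug sets by walking the graph from the rare disease and
#' intersects the non-empty ones:
#' \describe{
#'   \item{P1}{disease -> symptom -> drug: drugs indicated for a symptom of
#'     the rare disease.}
#'   \item{P2}{disease -> symptom -> disease -> drug: drugs indicated for a
#'     disease sharing at least one symptom.}
#'   \item{P3}{disease -> symptom -> disease -> gene -> target -> drug: drugs
#'     targeting proteins encoded by the genes of symptom-sharing diseases.}
#'   \item{P4}{disease -> gene -> disease -> drug: drugs indicated for a
#'     disease sharing at least one gene.}
#'   \item{P5}{disease -> gene -> protein -> drug: drugs targeting proteins
#'     encoded by the rare disease's own genes (identical to the direct
#'     approach by construction).}
#'   \item{P6}{disease -> gene -> protein -> interaction partner -> drug:
#'     drugs targeting interaction partners of those proteins.}
#' }
#'
#' @inheritParams triples_approach
#' @param restrict_nonrare Restrict intermediate diseases in P2-P4 to
#'   non-rare diseases (default `TRUE`); the rare disease itself is always
#'   excluded.
#' @return List with `per_path` (named list P1..P6) and `combined`.
#' @export
paths_approach <- function(g, rare_id, restrict_nonrare = TRUE) {
  assert_rare(g, rare_id)
  dg <- g$edges$disease_gene
  dsym <- g$edges$disease_symptom
  syms <- dsym$feature_id[dsym$disease_id == rare_id]
  genes <- dg$feature_id[dg$disease_id == rare_id]

  sharing <- function(edge, feats) {
    ids <- unique(edge$disease_id[edge$feature_id %in% feats])
    ids <- setdiff(ids, rare_id)
    if (restrict_nonrare) ids <- intersect(ids, nonrare_ids(g))
    ids
  }
  sym_sharers <- sharing(dsym, syms)
  gene_sharers <- sharing(dg, genes)

  drugs_targeting <- function(prots) {
    e <- g$edges$drug_target
    set_sorted(e$drug_id[e$node_id %in% prots])
  }

  p1 <- drugs_indicated_for(g, syms)
  p2 <- drugs_indicated_for(g, sym_sharers)
  p3 <- drugs_targeting(encoded_proteins(
    g, dg$feature_id[dg$disease_id %in% sym_sharers]))
  p4 <- drugs_indicated_for(g, gene_sharers)
  own_prots <- encoded_proteins(g, genes)
  p5 <- drugs_targeting(own_prots)
  partners <- set_sorted(unlist(lapply(own_prots, ppi_neighbors, g = g)))
  p6 <- drugs_targeting(partners)

  per_path <- list(P1 = p1, P2 = p2, P3 = p3, P4 = p4, P5 = p5, P6 = p6)
  list(per_path = per_path, combined = intersect_nonempty(per_path))
}

#' Combine per-approach candidate sets
#'
#' Intersects the non-empty candidate sets. `all` intersects over all four
#' approaches; `ttddrp` over the target-constrained triples, direct, and
#' paths approaches only (dropping the more generalist plain-triples set).
#' When exactly one member set is non-empty it passes through unchanged; when
#' all members are empty the result is empty.
#'
#' @param per_approach Named list with members `triples`, `triples_target`,
#'   `direct`, `paths`, each a character vector of drug ids.
#' @return List with `all` and `ttddrp` drug sets (sorted).
#' @export
combine_approaches <- function(per_approach) {
  need <- c("triples", "triples_target", "direct", "paths")
  missing <- setdiff(need, names(per_approach))
  if (length(missing)) {
    abort_config(sprintf("per_approach is missing '%s'", missing[1]))
  }
  list(all = intersect_nonempty(per_approach[need]),
       ttddrp = intersect_nonempty(per_approach[c("triples_target", "direct", "paths")]))
}

#' Run all four approaches for a set of rare diseases
#'
#' Computes, per rare disease, the candidate drug sets of the four
#' approaches, the per-feature and per-path intermediate sets, and the two
#' combined intersections. Drugs already indicated for the rare disease are
#' flagged as known treatments and excluded from every candidate set
#' (repositioning proposes new indications), unless `exclude_known = FALSE`.
#'
#' @param g A `knowledge_graph`.
#' @param rare_ids Rare disease ids to analyse.
#' @param k,share_min Passed to the triples approaches.
#' @param restrict_nonrare Passed to [paths_approach()].
#' @param exclude_known Drop drugs already indicated for the disease.
#' @return List with `results` (named list of per-disease approach results)
#'   and `summary` (tibble of per-approach and combined candidate counts,
#'   one row per disease).
#' @export
run_all <- function(g, rare_ids, k = 5, share_min = 2,
                    restrict_nonrare = TRUE, exclude_known = TRUE) {
  results <- lapply(stats::setNames(rare_ids, rare_ids), function(r) {
    tri <- triples_approach(g, r, k = k, share_min = share_min)
    tt <- triples_target_approach(g, r, k = k, share_min = share_min)
    dir <- direct_approach(g, r)
    pth <- paths_approach(g, r, restrict_nonrare = restrict_nonrare)
    known <- drugs_indicated_for(g, r)
    strip <- if (exclude_known && length(known)) {
      function(s) setdiff(s, known)
    } else identity
    per_approach <- list(triples = strip(tri$combined),
                         triples_target = strip(tt$combined),
                         direct = strip(dir),
                         paths = strip(pth$combined))
    comb <- combine_approaches(per_approach)
    structure(list(
      rare_id = r,
      per_approach = per_approach,
      per_feature_triples = lapply(tri$per_feature, strip),
      per_feature_triples_union = set_sorted(unlist(lapply(tri$per_feature, strip))),
      per_path = lapply(pth$per_path, strip),
      known_treatments = known,
      all_combined = comb$all,
      ttddrp_combined = comb$ttddrp
    ), class = "approach_result")
  })
  summary <- dplyr::bind_rows(lapply(results, function(res) {
    tibble::tibble(
      rare_id = res$rare_id,
      triples = length(res$per_approach$triples),
      triples_union = length(res$per_feature_triples_union),
      triples_target = length(res$per_approach$triples_target),
      direct = length(res$per_approach$direct),
      paths = length(res$per_approach$paths),
      all = length(res$all_combined),
      ttddrp = length(res$ttddrp_combined)
    )
  }))
  list(results = results, summary = summary)
}
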