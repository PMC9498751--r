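# Feature-wise Jaccard disease similarity and deterministic top-k rankings.

#' Jaccard similarity of two finite sets
#'
#' `|A intersect B| / |A union B|`, with the convention that two empty sets
#' have similarity 0. Symmetric; 1 exactly for equal non-empty sets; 0 for
#' disjoint sets.
#'
#' @param a,b Character vectors treated as sets (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Similarity of every rare/non-rare disease pair for one feature
#'
#' Matches each given rare disease against every non-rare disease in the
#' graph and scores the pair by the Jaccard similarity of their feature sets.
#' The full table is both the source of the top-k rankings and the background
#' distribution for the downstream phenotypic-similarity test.
#'
#' @param g A `knowledge_graph`.
#' @param rare_ids Non-empty vector of rare disease identifiers.
#' @param feature One of [feature_kinds()].
#' @return Tibble with columns `rare_id`, `nonrare_id`, `feature`, `score`,
#'   one row per (rare, non-rare) pair.
#' @export
all_pair_similarities <- function(g, rare_ids, feature) {
  feature <- match.arg(feature, feature_kinds())
  if (length(rare_ids) == 0) abort_config("rare_ids must be non-empty")
  unknown <- setdiff(rare_ids, g$diseases$id)
  if (length(unknown)) abort_lookup(sprintf("unknown disease '%s'", unknown[1]))
  prof <- profiles_by_feature(g, feature)
  nr <- nonrare_ids(g)
  out <- lapply(rare_ids, function(r) {
    a <- prof[[r]]
    tibble::tibble(
      rare_id = r,
      nonrare_id = nr,
      feature = feature,
      score = vapply(nr, function(n) jaccard(a, prof[[n]]), numeric(1),
                     USE.NAMES = FALSE)
    )
  })
  dplyr::bind_rows(out)
}

#' Top-k most similar non-rare diseases for one rare disease
#'
#' Ranks all non-rare diseases by feature-set Jaccard similarity to the rare
#' disease. Scores are non-increasing, ties are broken by ascending non-rare
#' disease id, zero-score neighbours are excluded, and ties crossing the k-th
#' rank are truncated after the id tie-break (a message notes when this
#' happens), so the result is deterministic with at most `k` rows.
#'
#' @param g A `knowledge_graph`.
#' @param rare_id A rare disease identifier declared in `g`.
#' @param feature One of [feature_kinds()].
#' @param k Maximum number of neighbours (default 5).
#' @return Tibble with columns `nonrare_id`, `score`, at most `k` rows.
#' @export
rank_neighbors <- function(g, rare_id, feature, k = 5) {
  feature <- match.arg(feature, feature_kinds())
  if (!rare_id %in% g$diseases$id) {
    abort_lookup(sprintf("unknown disease '%s'", rare_id))
  }
  sims <- all_pair_similarities(g, rare_id, feature)
  sims <- sims[sims$score > 0, c("nonrare_id", "score")]
  sims <- sims[order(-sims$score, sims$nonrare_id), ]
  if (nrow(sims) > k && sims$score[k] == sims$score[k + 1]) {
    rlang::inform(sprintf(
      "rank_neighbors: score tie at rank %d for '%s'/%s truncated by id order",
      k, rare_id, feature))
  }
  utils::head(sims, k)
}
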