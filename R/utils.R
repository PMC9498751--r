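# Shared vocabularies and small internal helpers.

#' Biological feature kinds used for disease similarity
#'
#' The five feature kinds over which disease profiles and Jaccard similarities
#' are computed: genes, symptoms, proteins, pathways, and variants.
#'
#' @return Character vector of the five feature kind labels.
#' @export
feature_kinds <- function() {
  c("gene", "symptom", "protein", "pathway", "variant")
}

#' Orphanet-style prevalence classes
#'
#' The closed vocabulary of point-prevalence classes attached to disease nodes,
#' ordered from most to least prevalent, plus the collapsed `"unknown"` class
#' (the three undocumented variants -- Null, Unknown, Not yet documented --
#' all map to `"unknown"`).
#'
#' @return Character vector of the seven prevalence class labels.
#' @export
prevalence_classes <- function() {
  c(">1/1000", "6-9/10000", "1-5/10000", "1-9/100000",
    "1-9/1000000", "<1/1000000", "unknown")
}

#' ATC first-level anatomical/pharmacological groups
#'
#' @return The 14 valid first letters of WHO ATC codes.
#' @export
atc_level1_letters <- function() {
  c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")
}

# Canonical set representation: sorted unique character vector.
set_sorted <- function(x) {
  if (length(x) == 0) return(character())
  sort(unique(as.character(x)))
}

# Classed conditions so callers/tests can distinguish failure modes.
abort_config <- function(msg) {
  rlang::abort(msg, class = "raredr_config_error")
}
abort_validation <- function(msg) {
  rlang::abort(msg, class = "raredr_validation_error")
}
abort_lookup <- function(msg) {
  rlang::abort(msg, class = "raredr_lookup_error")
}

# Deterministic per-component sub-seed derived from one global seed, so adding
# a generator component does not perturb the draws of the others.
substream_seed <- function(seed, component) {
  codes <- utf8ToInt(component)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h * 613) %% 2147483629L
}

collapse_unknown_prevalence <- function(x) {
  x <- as.character(x)
  x[x %in% c("Null", "Unknown", "Not yet documented", "", NA_character_)] <- "unknown"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
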