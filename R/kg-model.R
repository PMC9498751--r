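# Knowledge-graph data model: typed node tables, named edge sets, validation,
# and the ten-file TSV reader/writer.

EDGE_NAMES <- c("disease_gene", "disease_symptom", "disease_protein",
                "disease_pathway", "disease_variant", "drug_indication",
                "drug_target", "gene_protein", "ppi", "gda")

NODE_ROLES <- c("gene", "symptom", "protein", "pathway", "variant")

empty_edge <- function(name) {
  switch(name,
    drug_indication = ,
    drug_target = tibble::tibble(drug_id = character(), node_id = character()),
    gene_protein = tibble::tibble(gene_id = character(), protein_id = character()),
    ppi = tibble::tibble(protein_a = character(), protein_b = character()),
    gda = tibble::tibble(gene_id = character(), disease_id = character(),
                         gda_score = double(), dsi = double(), dpi = double()),
    tibble::tibble(disease_id = character(), feature_id = character())
  )
}

dedup_edges <- function(df, name) {
  n0 <- nrow(df)
  df <- dplyr::distinct(df)
  if (nrow(df) < n0) {
    rlang::warn(sprintf("%d duplicate rows dropped from edge set '%s'",
                        n0 - nrow(df), name))
  }
  df
}

#' Construct a validated knowledge graph
#'
#' Builds the immutable container holding all node tables and association edge
#' sets used by every downstream stage: disease similarity, the four
#' candidate-generation approaches, and the validation statistics. Edge rows
#' are deduplicated (with a warning), protein-protein interaction pairs are
#' stored order-independently, tables are put into a canonical sort, and all
#' referential-integrity invariants are checked.
#'
#' @param diseases Data frame with columns `id`, `name`, `is_rare` (logical),
#'   `prevalence_class` (one of [prevalence_classes()]; the Orphanet unknown
#'   variants collapse to `"unknown"`), `prevalence_geography`.
#' @param drugs Data frame with columns `id`, `name`, `atc_codes`
#'   (semicolon-joined ATC level-5 codes, possibly empty).
#' @param nodes Data frame with columns `id`, `role` (one of gene, symptom,
#'   protein, pathway, variant).
#' @param edges Named list of edge data frames; any of `disease_gene`,
#'   `disease_symptom`, `disease_protein`, `disease_pathway`,
#'   `disease_variant` (`disease_id`, `feature_id`), `drug_indication`,
#'   `drug_target` (`drug_id`, `node_id`), `gene_protein`
#'   (`gene_id`, `protein_id`), `ppi` (`protein_a`, `protein_b`), and `gda`
#'   (`gene_id`, `disease_id`, `gda_score`, `dsi`, `dpi`). Missing members
#'   default to empty.
#'
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(diseases, drugs, nodes, edges = list()) {
  diseases <- tibble::as_tibble(diseases)
  drugs <- tibble::as_tibble(drugs)
  nodes <- tibble::as_tibble(nodes)
  if (!"atc_codes" %in% names(drugs)) drugs$atc_codes <- ""
  drugs$atc_codes[is.na(drugs$atc_codes)] <- ""
  diseases$prevalence_class <- collapse_unknown_prevalence(diseases$prevalence_class)
  diseases$is_rare <- as.logical(diseases$is_rare)

  full_edges <- lapply(stats::setNames(EDGE_NAMES, EDGE_NAMES), function(nm) {
    df <- edges[[nm]]
    if (is.null(df) || nrow(df) == 0) return(empty_edge(nm))
    df <- tibble::as_tibble(df)
    if (nm == "ppi") {
      # store unordered pairs canonically so (p, q) and (q, p) are one edge
      a <- pmin(df$protein_a, df$protein_b)
      b <- pmax(df$protein_a, df$protein_b)
      df <- tibble::tibble(protein_a = a, protein_b = b)
    }
    dedup_edges(df, nm)
  })

  g <- structure(
    list(
      diseases = dplyr::arrange(diseases, .data$id),
      drugs = dplyr::arrange(drugs, .data$id),
      nodes = dplyr::arrange(nodes, .data$id),
      edges = lapply(full_edges, function(df) dplyr::arrange(df, !!!rlang::syms(names(df))))
    ),
    class = "knowledge_graph"
  )
  validate_graph(g)
  g
}

#' Validate knowledge-graph invariants
#'
#' Checks identifier uniqueness, the closed prevalence-class vocabulary, ATC
#' code shape (7 characters, first letter one of the 14 anatomical groups),
#' node roles, score ranges of gene-disease association records, and
#' referential integrity of every edge endpoint. Called by [knowledge_graph()]
#' and [load_graph()]; exported so hand-modified graphs can be re-checked.
#'
#' @param g A `knowledge_graph`.
#' @return `g`, invisibly, if valid; otherwise a validation error naming the
#'   offending edge set and endpoint.
#' @export
validate_graph <- function(g) {
  d <- g$diseases
  if (any(is.na(d$id)) || any(d$id == "")) {
    abort_validation("disease ids must be non-empty")
  }
  if (anyDuplicated(d$id)) {
    abort_validation(sprintf("duplicate disease id '%s'", d$id[duplicated(d$id)][1]))
  }
  bad_prev <- setdiff(unique(d$prevalence_class), prevalence_classes())
  if (length(bad_prev)) {
    abort_validation(sprintf("malformed prevalence class '%s'", bad_prev[1]))
  }
  if (anyDuplicated(g$drugs$id)) abort_validation("duplicate drug id")
  if (anyDuplicated(g$nodes$id)) abort_validation("duplicate node id")
  bad_role <- setdiff(unique(g$nodes$role), NODE_ROLES)
  if (length(bad_role)) {
    abort_validation(sprintf("unknown node role '%s'", bad_role[1]))
  }
  codes <- unlist(split_atc(g$drugs$atc_codes), use.names = FALSE)
  if (length(codes)) {
    if (any(nchar(codes) != 7)) {
      abort_validation(sprintf("ATC code '%s' is not 7 characters",
                               codes[nchar(codes) != 7][1]))
    }
    bad <- setdiff(substr(codes, 1, 1), atc_level1_letters())
    if (length(bad)) {
      abort_validation(sprintf("ATC level-1 letter '%s' is not a valid anatomical group", bad[1]))
    }
  }

  role_ids <- split(g$nodes$id, factor(g$nodes$role, levels = NODE_ROLES))
  check_ref <- function(values, universe, edge, col) {
    missing <- setdiff(unique(values), universe)
    if (length(missing)) {
      abort_validation(sprintf(
        "edge set '%s' references undeclared %s '%s'", edge, col, missing[1]))
    }
  }
  for (feat in NODE_ROLES) {
    nm <- paste0("disease_", feat)
    e <- g$edges[[nm]]
    check_ref(e$disease_id, d$id, nm, "disease")
    check_ref(e$feature_id, role_ids[[feat]], nm, feat)
  }
  e <- g$edges$drug_indication
  check_ref(e$drug_id, g$drugs$id, "drug_indication", "drug")
  check_ref(e$node_id, c(d$id, role_ids$symptom), "drug_indication", "indication concept")
  e <- g$edges$drug_target
  check_ref(e$drug_id, g$drugs$id, "drug_target", "drug")
  check_ref(e$node_id, role_ids$protein, "drug_target", "protein")
  e <- g$edges$gene_protein
  check_ref(e$gene_id, role_ids$gene, "gene_protein", "gene")
  check_ref(e$protein_id, role_ids$protein, "gene_protein", "protein")
  e <- g$edges$ppi
  check_ref(c(e$protein_a, e$protein_b), role_ids$protein, "ppi", "protein")
  e <- g$edges$gda
  check_ref(e$gene_id, role_ids$gene, "gda", "gene")
  check_ref(e$disease_id, d$id, "gda", "disease")
  scores <- c(e$gda_score, e$dsi, e$dpi)
  if (length(scores) && (any(is.na(scores)) || any(scores < 0) || any(scores > 1))) {
    abort_validation("gda scores (gda_score, dsi, dpi) must lie in [0, 1]")
  }
  invisible(g)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d diseases (%d rare), %d drugs, %d feature nodes\n",
              nrow(x$diseases), sum(x$diseases$is_rare), nrow(x$drugs), nrow(x$nodes)))
  counts <- vapply(x$edges, nrow, integer(1))
  cat("edges:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

split_atc <- function(x) {
  if (length(x) == 0) return(list())
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[v != ""])
}

graph_files <- function() {
  c(diseases = "diseases.tsv", drugs = "drugs.tsv", nodes = "nodes.tsv",
    disease_gene = "disease_gene.tsv", disease_symptom = "disease_symptom.tsv",
    disease_protein = "disease_protein.tsv", disease_pathway = "disease_pathway.tsv",
    disease_variant = "disease_variant.tsv", drug_edges = "drug_edges.tsv",
    gene_protein = "gene_protein.tsv", ppi = "ppi.tsv", gda = "gda.tsv")
}

#' Load a knowledge graph from its TSV file set
#'
#' Reads the tab-delimited, UTF-8 edge-list file set (see [save_graph()] for
#' the layout) and returns a validated [knowledge_graph()]. Drug indication
#' and target edges share one file, `drug_edges.tsv`, with a `kind` column.
#'
#' @param dir Directory containing the file set.
#' @return A `knowledge_graph`.
#' @export
load_graph <- function(dir) {
  files <- file.path(dir, graph_files())
  names(files) <- names(graph_files())
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    abort_config(sprintf("missing graph file '%s'", missing[1]))
  }
  rd <- function(path, types) {
    readr::read_tsv(path, col_types = types, progress = FALSE)
  }
  diseases <- rd(files["diseases"], readr::cols(
    id = "c", name = "c", is_rare = "l", prevalence_class = "c",
    prevalence_geography = "c"))
  drugs <- rd(files["drugs"], readr::cols(id = "c", name = "c", atc_codes = "c"))
  nodes <- rd(files["nodes"], readr::cols(id = "c", role = "c"))
  fe <- function(key) rd(files[key], readr::cols(disease_id = "c", feature_id = "c"))
  drug_edges <- rd(files["drug_edges"], readr::cols(drug_id = "c", kind = "c", node_id = "c"))
  bad_kind <- setdiff(unique(drug_edges$kind), c("indication", "target"))
  if (length(bad_kind)) {
    abort_validation(sprintf("unknown drug edge kind '%s'", bad_kind[1]))
  }
  edges <- list(
    disease_gene = fe("disease_gene"),
    disease_symptom = fe("disease_symptom"),
    disease_protein = fe("disease_protein"),
    disease_pathway = fe("disease_pathway"),
    disease_variant = fe("disease_variant"),
    drug_indication = drug_edges[drug_edges$kind == "indication", c("drug_id", "node_id")],
    drug_target = drug_edges[drug_edges$kind == "target", c("drug_id", "node_id")],
    gene_protein = rd(files["gene_protein"], readr::cols(gene_id = "c", protein_id = "c")),
    ppi = rd(files["ppi"], readr::cols(protein_a = "c", protein_b = "c")),
    gda = rd(files["gda"], readr::cols(gene_id = "c", disease_id = "c",
                                       gda_score = "d", dsi = "d", dpi = "d"))
  )
  knowledge_graph(diseases, drugs, nodes, edges)
}

#' Write a knowledge graph as its TSV file set
#'
#' Emits ten tab-delimited UTF-8 files with headers: `diseases.tsv`,
#' `drugs.tsv`, `nodes.tsv`, one file per disease-feature edge set,
#' `drug_edges.tsv` (indication and target edges with a `kind` column),
#' `gene_protein.tsv`, `ppi.tsv`, and `gda.tsv`. Rows are written in a fixed
#' canonical sort so the file set is byte-stable: saving, loading, and saving
#' again reproduces identical files.
#'
#' @param g A `knowledge_graph`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
save_graph <- function(g, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create directory '%s'", dir),
                          class = "raredr_io_error")
  }
  files <- file.path(dir, graph_files())
  names(files) <- names(graph_files())
  wr <- function(df, path) readr::write_tsv(df, path, progress = FALSE)
  wr(g$diseases, files["diseases"])
  wr(g$drugs, files["drugs"])
  wr(g$nodes, files["nodes"])
  for (feat in NODE_ROLES) {
    wr(g$edges[[paste0("disease_", feat)]], files[paste0("disease_", feat)])
  }
  ind <- g$edges$drug_indication
  tgt <- g$edges$drug_target
  drug_edges <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(drug_id = ind$drug_id, kind = "indication", node_id = ind$node_id),
    tibble::tibble(drug_id = tgt$drug_id, kind = "target", node_id = tgt$node_id)
  ), .data$drug_id, .data$kind, .data$node_id)
  wr(drug_edges, files["drug_edges"])
  wr(g$edges$gene_protein, files["gene_protein"])
  wr(g$edges$ppi, files["ppi"])
  wr(g$edges$gda, files["gda"])
  invisible(files)
}

#' Per-disease feature profile
#'
#' Returns the five feature sets of one disease -- its associated genes,
#' symptoms, proteins, pathways, and variants -- read directly off the graph's
#' edge sets. These are the sets A and B entering the Jaccard similarity.
#'
#' @param g A `knowledge_graph`.
#' @param disease_id Declared disease identifier.
#' @return Named list of five sorted character vectors
#'   (`genes`, `symptoms`, `proteins`, `pathways`, `variants`).
#' @export
feature_profile <- function(g, disease_id) {
  if (!disease_id %in% g$diseases$id) {
    abort_lookup(sprintf("unknown disease '%s'", disease_id))
  }
  out <- lapply(NODE_ROLES, function(feat) {
    e <- g$edges[[paste0("disease_", feat)]]
    set_sorted(e$feature_id[e$disease_id == disease_id])
  })
  names(out) <- c("genes", "symptoms", "proteins", "pathways", "variants")
  out
}

# Named list disease_id -> sorted feature set for one feature kind; diseases
# with no edges map to character(0). Internal fast path for similarity.
profiles_by_feature <- function(g, feature) {
  e <- g$edges[[paste0("disease_", feature)]]
  out <- lapply(split(e$feature_id, e$disease_id), set_sorted)
  absent <- setdiff(g$diseases$id, names(out))
  out[absent] <- list(character())
  out
}

#' Protein interaction partners
#'
#' Order-independent neighbour query over the protein-protein interaction
#' edge set: the partners of `p` contain `q` exactly when the partners of `q`
#' contain `p`.
#'
#' @param g A `knowledge_graph`.
#' @param protein_id Protein identifier.
#' @return Sorted character vector of interaction partners.
#' @export
ppi_neighbors <- function(g, protein_id) {
  e <- g$edges$ppi
  set_sorted(c(e$protein_b[e$protein_a == protein_id],
               e$protein_a[e$protein_b == protein_id]))
}

# drug -> sorted protein target set
drug_target_map <- function(g) {
  e <- g$edges$drug_target
  lapply(split(e$node_id, e$drug_id), set_sorted)
}

# disease/symptom concept -> drugs indicated for it
drugs_indicated_for <- function(g, concept_ids) {
  e <- g$edges$drug_indication
  set_sorted(e$drug_id[e$node_id %in% concept_ids])
}

# gene -> proteins it encodes
encoded_proteins <- function(g, gene_ids) {
  e <- g$edges$gene_protein
  set_sorted(e$protein_id[e$gene_id %in% gene_ids])
}

rare_ids <- function(g) g$diseases$id[g$diseases$is_rare]
nonrare_ids <- function(g) g$diseases$id[!g$diseases$is_rare]
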