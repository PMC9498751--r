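# Independent brute-force oracles: plain-loop re-derivations of every
# candidate-generation approach, working directly off the graph's edge
# tables. Deliberately naive and kept separate from the package's own code
# paths.

oracle_jaccard <- function(a, b) {
  u <- union(unique(a), unique(b))
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

oracle_profile <- function(g, id, feat) {
  e <- g$edges[[paste0("disease_", feat)]]
  sort(unique(e$feature_id[e$disease_id == id]))
}

oracle_rank <- function(g, rare, feat, k = 5) {
  nr <- g$diseases$id[!g$diseases$is_rare]
  a <- oracle_profile(g, rare, feat)
  score <- vapply(nr, function(n) oracle_jaccard(a, oracle_profile(g, n, feat)),
                  numeric(1))
  df <- data.frame(nonrare_id = nr, score = unname(score))
  df <- df[df$score > 0, , drop = FALSE]
  df <- df[order(-df$score, df$nonrare_id), , drop = FALSE]
  utils::head(df, k)
}

oracle_indicated <- function(g, concepts) {
  e <- g$edges$drug_indication
  sort(unique(e$drug_id[e$node_id %in% concepts]))
}

oracle_enc <- function(g, genes) {
  e <- g$edges$gene_protein
  sort(unique(e$protein_id[e$gene_id %in% genes]))
}

oracle_targeting <- function(g, prots) {
  e <- g$edges$drug_target
  sort(unique(e$drug_id[e$node_id %in% prots]))
}

oracle_direct <- function(g, rare) {
  oracle_targeting(g, oracle_enc(g, oracle_profile(g, rare, "gene")))
}

oracle_intersect_nonempty <- function(sets) {
  sets <- Filter(length, sets)
  if (length(sets) == 0) return(character())
  sort(Reduce(intersect, sets))
}

oracle_triples <- function(g, rare, k = 5, share_min = 2, constrain = FALSE) {
  feats <- c("gene", "symptom", "protein", "pathway", "variant")
  per <- lapply(feats, function(f) {
    top <- oracle_rank(g, rare, f, k)
    if (nrow(top) == 0) return(character())
    tally <- numeric(0)
    for (n in top$nonrare_id) {
      drugs <- oracle_indicated(g, n)
      if (constrain) {
        shared <- intersect(oracle_profile(g, rare, "gene"),
                            oracle_profile(g, n, "gene"))
        sp <- oracle_enc(g, shared)
        keep <- logical(length(drugs))
        for (i in seq_along(drugs)) {
          tg <- g$edges$drug_target$node_id[g$edges$drug_target$drug_id == drugs[i]]
          keep[i] <- length(intersect(tg, sp)) > 0
        }
        drugs <- drugs[keep]
      }
      for (d in drugs) {
        if (is.na(tally[d])) tally[d] <- 1 else tally[d] <- tally[d] + 1
      }
    }
    sort(as.character(names(tally)[tally >= share_min]))
  })
  names(per) <- feats
  list(per_feature = per, combined = oracle_intersect_nonempty(per))
}

oracle_paths <- function(g, rare) {
  nr <- g$diseases$id[!g$diseases$is_rare]
  syms <- oracle_profile(g, rare, "symptom")
  genes <- oracle_profile(g, rare, "gene")
  dsym <- g$edges$disease_symptom
  dg <- g$edges$disease_gene
  sym_sharers <- setdiff(intersect(unique(dsym$disease_id[dsym$feature_id %in% syms]), nr), rare)
  gene_sharers <- setdiff(intersect(unique(dg$disease_id[dg$feature_id %in% genes]), nr), rare)
  own_prots <- oracle_enc(g, genes)
  partners <- character()
  for (p in own_prots) {
    e <- g$edges$ppi
    partners <- c(partners, e$protein_b[e$protein_a == p], e$protein_a[e$protein_b == p])
  }
  per <- list(
    P1 = oracle_indicated(g, syms),
    P2 = oracle_indicated(g, sym_sharers),
    P3 = oracle_targeting(g, oracle_enc(g, unique(dg$feature_id[dg$disease_id %in% sym_sharers]))),
    P4 = oracle_indicated(g, gene_sharers),
    P5 = oracle_targeting(g, own_prots),
    P6 = oracle_targeting(g, sort(unique(partners)))
  )
  list(per_path = per, combined = oracle_intersect_nonempty(per))
}

oracle_select <- function(g, criteria) {
  keep <- character()
  for (id in g$diseases$id) {
    row <- g$diseases[g$diseases$id == id, ]
    n_genes <- length(oracle_profile(g, id, "gene"))
    n_syms <- length(oracle_profile(g, id, "symptom"))
    n_any <- n_genes + n_syms +
      length(oracle_profile(g, id, "protein")) +
      length(oracle_profile(g, id, "pathway")) +
      length(oracle_profile(g, id, "variant"))
    treated <- id %in% g$edges$drug_indication$node_id
    ok <- TRUE
    if (criteria$require_rare && !row$is_rare) ok <- FALSE
    if (criteria$require_in_graph && n_any == 0) ok <- FALSE
    if (criteria$exclude_with_treatment && treated) ok <- FALSE
    if (criteria$require_genes_and_symptoms && (n_genes == 0 || n_syms == 0)) ok <- FALSE
    if (!is.null(criteria$geography_whitelist) &&
        !row$prevalence_geography %in% criteria$geography_whitelist) ok <- FALSE
    if (!is.null(criteria$prevalence_whitelist) &&
        !row$prevalence_class %in% criteria$prevalence_whitelist) ok <- FALSE
    if (!is.null(criteria$max_genes) && n_genes > criteria$max_genes) ok <- FALSE
    if (!is.null(criteria$max_symptoms) && n_syms > criteria$max_symptoms) ok <- FALSE
    if (ok) keep <- c(keep, id)
  }
  sort(keep)
}
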