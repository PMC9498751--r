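# Synthetic knowledge-graph generator: disease-knowledge-base-like background with
# controllable overlap plus planted repositioning signal, so every pipeline
# stage can be exercised and scored against known ground truth.

#' Generator configuration
#'
#' Parameters controlling the synthetic knowledge graph. Background diseases
#' draw feature-profile sizes uniformly from `profile_size_ranges` and sample
#' features with a shared-pool mechanism: with probability
#' `background_overlap` a feature comes from a small hub sub-vocabulary, so
#' unrelated diseases have small but non-zero Jaccard overlap. Planted
#' hypotheses copy a fraction `planted_overlap` of a rare disease's features
#' into each confederate non-rare disease and wire a drug so that every
#' candidate-generation approach can recover it (target protein encoded by a
#' gene shared between the rare disease and all confederates, indication
#' edges to all confederates and to one rare-disease symptom, and a
#' protein-interaction edge closing the interaction path).
#'
#' @param n_rare,n_nonrare Disease counts.
#' @param vocab_sizes Named counts of feature vocabularies
#'   (genes, symptoms, proteins, pathways, variants).
#' @param n_drugs Background drug count (planted drugs are added on top).
#' @param profile_size_ranges Named list of integer ranges (lo, hi) for
#'   per-disease profile sizes; defaults span the gene/symptom set sizes
#'   observed across well-annotated rare diseases (1-44 genes, up to a few
#'   hundred symptoms in the extreme).
#' @param background_overlap Probability in `[0, 1]` that a background
#'   feature draw comes from the hub pool.
#' @param n_planted Number of planted repositioning hypotheses.
#' @param planted_overlap Fraction in `(0, 1]` of the rare disease's features
#'   copied into each confederate; must exceed `background_overlap`.
#' @param confederates_per_plant Non-rare diseases sharing each planted drug.
#' @param gda_beta_planted,gda_beta_background Beta shape pairs for GDA
#'   scores of planted rare diseases' gene associations versus everything
#'   else.
#' @param hub_fraction Fraction of each vocabulary forming the shared hub pool.
#' @param seed Integer seed; one global seed feeds independent per-component
#'   substreams.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_rare = 10,
                             n_nonrare = 150,
                             vocab_sizes = c(genes = 400, symptoms = 300,
                                             proteins = 400, pathways = 150,
                                             variants = 250),
                             n_drugs = 60,
                             profile_size_ranges = list(
                               genes = c(1, 44), symptoms = c(2, 40),
                               proteins = c(1, 20), pathways = c(1, 12),
                               variants = c(1, 15)),
                             background_overlap = 0.1,
                             n_planted = 3,
                             planted_overlap = 0.9,
                             confederates_per_plant = 5,
                             gda_beta_planted = c(8, 2),
                             gda_beta_background = c(2, 8),
                             hub_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_rare = as.integer(n_rare), n_nonrare = as.integer(n_nonrare),
              vocab_sizes = vocab_sizes, n_drugs = as.integer(n_drugs),
              profile_size_ranges = profile_size_ranges,
              background_overlap = background_overlap,
              n_planted = as.integer(n_planted),
              planted_overlap = planted_overlap,
              confederates_per_plant = as.integer(confederates_per_plant),
              gda_beta_planted = gda_beta_planted,
              gda_beta_background = gda_beta_background,
              hub_fraction = hub_fraction,
              seed = as.integer(seed))
  counts <- c(cfg$n_rare, cfg$n_nonrare, cfg$n_drugs, cfg$confederates_per_plant,
              unlist(vocab_sizes))
  if (any(counts <= 0)) abort_config("all generator counts must be positive")
  if (cfg$n_planted < 0) abort_config("n_planted must be non-negative")
  if (!(cfg$planted_overlap > 0 && cfg$planted_overlap <= 1)) {
    abort_config("planted_overlap must lie in (0, 1]")
  }
  if (cfg$planted_overlap <= cfg$background_overlap) {
    abort_config("planted_overlap must exceed background_overlap (signal would be undetectable)")
  }
  for (r in profile_size_ranges) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      abort_config("profile_size_ranges must be (lo, hi) with 1 <= lo <= hi")
    }
  }
  if (cfg$n_planted > 0) {
    if (cfg$n_planted > cfg$n_rare) abort_config("n_planted exceeds n_rare")
    if (cfg$n_planted * cfg$confederates_per_plant > cfg$n_nonrare) {
      abort_config("not enough non-rare diseases for the requested confederates")
    }
  }
  structure(cfg, class = "generator_config")
}

FEATURE_PLURAL <- c(gene = "genes", symptom = "symptoms", protein = "proteins",
                    pathway = "pathways", variant = "variants")

random_atc_code <- function(n) {
  paste0(sample(atc_level1_letters(), n, replace = TRUE),
         sprintf("%02d", sample(1:16, n, replace = TRUE)),
         sample(LETTERS, n, replace = TRUE),
         sample(LETTERS, n, replace = TRUE),
         sprintf("%02d", sample(1:99, n, replace = TRUE)))
}

#' Generate a synthetic knowledge graph with planted ground truth
#'
#' Produces a validated [knowledge_graph()] together with its planted-truth
#' table. Construction guarantees, per plant: the shared gene belongs to the
#' rare disease and to every confederate; the planted drug targets the
#' protein encoded by that gene, is indicated for every confederate and for
#' one symptom of the rare disease, and a protein-interaction edge connects
#' the target protein to another protein encoded by the rare disease's genes.
#' As a consequence the planted drug is recoverable by the direct approach by
#' construction and by all six traversal paths, and each feature-wise Jaccard
#' between the rare disease and a confederate exceeds, in expectation, the
#' background level.
#'
#' @param config A [generator_config()].
#' @return List with elements `graph` (a `knowledge_graph`) and `planted`
#'   (tibble: `rare_disease_id`, `drug_id`, `confederate_ids`
#'   semicolon-joined, `shared_gene`).
#' @export
generate_graph <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort_config("config must be built with generator_config()")
  }
  vs <- config$vocab_sizes
  vocab <- list(
    gene = sprintf("G%05d", seq_len(vs[["genes"]])),
    symptom = sprintf("S%05d", seq_len(vs[["symptoms"]])),
    protein = sprintf("P%05d", seq_len(vs[["proteins"]])),
    pathway = sprintf("W%05d", seq_len(vs[["pathways"]])),
    variant = sprintf("V%05d", seq_len(vs[["variants"]]))
  )
  hub <- lapply(vocab, function(v) v[seq_len(max(1, ceiling(config$hub_fraction * length(v))))])

  rare <- sprintf("C9%06d", seq_len(config$n_rare))
  nonrare <- sprintf("C8%06d", seq_len(config$n_nonrare))
  disease_ids <- c(rare, nonrare)

  diseases <- tibble::tibble(
    id = disease_ids,
    name = c(sprintf("Synthetic rare disease %d", seq_len(config$n_rare)),
             sprintf("Synthetic common disease %d", seq_len(config$n_nonrare))),
    is_rare = rep(c(TRUE, FALSE), c(config$n_rare, config$n_nonrare)),
    prevalence_class = "unknown",
    prevalence_geography = "Worldwide"
  )
  withr::with_seed(substream_seed(config$seed, "diseases"), {
    diseases$prevalence_class[diseases$is_rare] <- "<1/1000000"
    diseases$prevalence_class[!diseases$is_rare] <-
      sample(c(">1/1000", "6-9/10000", "1-5/10000", "unknown"),
             config$n_nonrare, replace = TRUE)
    diseases$prevalence_geography <-
      sample(c("Worldwide", "Europe", "North America"),
             nrow(diseases), replace = TRUE, prob = c(0.7, 0.2, 0.1))
  })

  # background feature profiles: shared-pool draw per feature slot
  profiles <- withr::with_seed(substream_seed(config$seed, "features"), {
    out <- list()
    for (feat in names(vocab)) {
      rng <- config$profile_size_ranges[[FEATURE_PLURAL[[feat]]]]
      sizes <- sample(seq(rng[1], rng[2]), length(disease_ids), replace = TRUE)
      sizes <- pmin(sizes, length(vocab[[feat]]))
      out[[feat]] <- lapply(seq_along(disease_ids), function(i) {
        n_hub <- stats::rbinom(1, sizes[i], config$background_overlap)
        n_hub <- min(n_hub, length(hub[[feat]]))
        feats <- c(sample(hub[[feat]], n_hub),
                   sample(setdiff(vocab[[feat]], hub[[feat]]), sizes[i] - n_hub))
        set_sorted(feats)
      })
      names(out[[feat]]) <- disease_ids
    }
    out
  })

  # every gene encodes one protein (round-robin), so gene->protein chains exist
  n_genes <- length(vocab$gene)
  n_prot <- length(vocab$protein)
  gene_protein <- tibble::tibble(
    gene_id = vocab$gene,
    protein_id = vocab$protein[((seq_len(n_genes) - 1L) %% n_prot) + 1L]
  )
  enc <- stats::setNames(gene_protein$protein_id, gene_protein$gene_id)

  withr::with_seed(substream_seed(config$seed, "ppi"), {
    m <- 2L * n_prot
    ppi <- tibble::tibble(
      protein_a = sample(vocab$protein, m, replace = TRUE),
      protein_b = sample(vocab$protein, m, replace = TRUE)
    )
    ppi <- ppi[ppi$protein_a != ppi$protein_b, ]
  })

  # background drugs with ATC codes, random targets, random indications
  drug_tbl <- withr::with_seed(substream_seed(config$seed, "drugs"), {
    ids <- sprintf("D%04d", seq_len(config$n_drugs))
    n_codes <- sample(0:2, config$n_drugs, replace = TRUE, prob = c(0.15, 0.6, 0.25))
    codes <- vapply(n_codes, function(k) paste(random_atc_code(k), collapse = ";"), "")
    targets <- lapply(ids, function(d) sample(vocab$protein, sample(1:3, 1)))
    ind_dis <- lapply(ids, function(d) sample(nonrare, sample(1:3, 1)))
    ind_sym <- lapply(ids, function(d) sample(vocab$symptom, sample(0:2, 1)))
    list(ids = ids, codes = codes, targets = targets,
         ind = mapply(c, ind_dis, ind_sym, SIMPLIFY = FALSE))
  })

  drug_target <- tibble::tibble(
    drug_id = rep(drug_tbl$ids, lengths(drug_tbl$targets)),
    node_id = unlist(drug_tbl$targets)
  )
  drug_indication <- tibble::tibble(
    drug_id = rep(drug_tbl$ids, lengths(drug_tbl$ind)),
    node_id = unlist(drug_tbl$ind)
  )
  drugs <- tibble::tibble(id = drug_tbl$ids,
                          name = sprintf("Synthetic drug %s", drug_tbl$ids),
                          atc_codes = drug_tbl$codes)

  planted <- tibble::tibble(rare_disease_id = character(), drug_id = character(),
                            confederate_ids = character(), shared_gene = character())

  if (config$n_planted > 0) {
    plant <- withr::with_seed(substream_seed(config$seed, "plants"), {
      planted_rare <- sample(rare, config$n_planted)
      confs <- split(sample(nonrare, config$n_planted * config$confederates_per_plant),
                     rep(seq_len(config$n_planted), each = config$confederates_per_plant))
      rows <- vector("list", config$n_planted)
      extra_ppi <- list()
      for (p in seq_len(config$n_planted)) {
        r <- planted_rare[p]
        # planted rare diseases carry >=3 genes so downstream GDA tests have
        # a non-degenerate hypothesis sample
        while (length(profiles$gene[[r]]) < 3) {
          profiles$gene[[r]] <- set_sorted(c(profiles$gene[[r]], sample(vocab$gene, 1)))
        }
        g_star <- sample(profiles$gene[[r]], 1)
        p_star <- enc[[g_star]]
        others <- setdiff(profiles$gene[[r]], g_star)
        g2 <- others[enc[others] != p_star][1]
        if (is.na(g2)) { # all genes encode p_star: attach a fresh gene
          g2 <- sample(vocab$gene[enc != p_star], 1)
          profiles$gene[[r]] <- set_sorted(c(profiles$gene[[r]], g2))
        }
        extra_ppi[[p]] <- c(p_star, enc[[g2]])

        for (conf in confs[[p]]) {
          for (feat in names(vocab)) {
            rset <- profiles[[feat]][[r]]
            if (feat == "gene") rset <- set_sorted(c(rset, g_star))
            n_copy <- max(1L, round(config$planted_overlap * length(rset)))
            copied <- sample(rset, min(n_copy, length(rset)))
            own <- setdiff(profiles[[feat]][[conf]], rset)
            keep_own <- utils::head(own, max(0L, length(rset) - length(copied)))
            newset <- set_sorted(c(copied, keep_own))
            if (feat == "gene") newset <- set_sorted(c(newset, g_star))
            profiles[[feat]][[conf]] <- newset
          }
        }
        rows[[p]] <- tibble::tibble(
          rare_disease_id = r,
          drug_id = sprintf("D9%03d", p),
          confederate_ids = paste(sort(confs[[p]]), collapse = ";"),
          shared_gene = g_star
        )
      }
      list(rows = dplyr::bind_rows(rows), confs = confs, extra_ppi = extra_ppi,
           profiles = profiles)
    })
    profiles <- plant$profiles
    planted <- plant$rows

    for (p in seq_len(nrow(planted))) {
      r <- planted$rare_disease_id[p]
      d <- planted$drug_id[p]
      g_star <- planted$shared_gene[p]
      p_star <- enc[[g_star]]
      drugs <- dplyr::bind_rows(drugs, tibble::tibble(
        id = d, name = sprintf("Planted drug %d", p),
        atc_codes = withr::with_seed(substream_seed(config$seed, paste0("atc", p)),
                                     random_atc_code(1))))
      drug_target <- dplyr::bind_rows(drug_target,
        tibble::tibble(drug_id = d, node_id = p_star))
      sym <- profiles$symptom[[r]][1]
      drug_indication <- dplyr::bind_rows(drug_indication, tibble::tibble(
        drug_id = d,
        node_id = c(strsplit(planted$confederate_ids[p], ";")[[1]], sym)))
      ppi <- dplyr::bind_rows(ppi, tibble::tibble(
        protein_a = plant$extra_ppi[[p]][1], protein_b = plant$extra_ppi[[p]][2]))
    }
  }

  # normalise + dedup ppi here so the constructor's duplicate warning stays
  # meaningful for user-supplied inputs
  ppi <- dplyr::distinct(tibble::tibble(
    protein_a = pmin(ppi$protein_a, ppi$protein_b),
    protein_b = pmax(ppi$protein_a, ppi$protein_b)))

  feat_edges <- lapply(names(vocab), function(feat) {
    pr <- profiles[[feat]]
    tibble::tibble(disease_id = rep(names(pr), lengths(pr)),
                   feature_id = unlist(pr, use.names = FALSE))
  })
  names(feat_edges) <- paste0("disease_", names(vocab))

  dg <- feat_edges$disease_gene
  planted_rare_set <- planted$rare_disease_id
  gda <- withr::with_seed(substream_seed(config$seed, "gda"), {
    hi <- dg$disease_id %in% planted_rare_set
    shp_h <- config$gda_beta_planted
    shp_l <- config$gda_beta_background
    tibble::tibble(
      gene_id = dg$feature_id,
      disease_id = dg$disease_id,
      gda_score = round(ifelse(hi, stats::rbeta(nrow(dg), shp_h[1], shp_h[2]),
                               stats::rbeta(nrow(dg), shp_l[1], shp_l[2])), 4),
      dsi = round(stats::runif(nrow(dg)), 4),
      dpi = round(stats::runif(nrow(dg)), 4)
    )
  })

  nodes <- tibble::tibble(
    id = unlist(vocab, use.names = FALSE),
    role = rep(names(vocab), lengths(vocab))
  )

  graph <- knowledge_graph(
    diseases, drugs, nodes,
    c(feat_edges, list(drug_indication = drug_indication,
                       drug_target = drug_target,
                       gene_protein = gene_protein, ppi = ppi, gda = gda)))
  list(graph = graph, planted = planted)
}

#' Thirteen-rare-disease study fixture
#'
#' Builds a graph containing 13 rare diseases with fixed concept identifiers
#' and exact gene/symptom profile sizes matching a well-characterised study
#' panel (e.g. Schwartz-Jampel syndrome with 23 genes and 5 symptoms, diffuse
#' cutaneous mastocytosis with 1 gene and 237 symptoms), over synthetic
#' feature identifiers, plus a configurable non-rare background.
#'
#' @param n_nonrare Background non-rare disease count.
#' @param seed Seed for the background.
#' @return A `knowledge_graph` whose 13 rare diseases have exactly the fixed
#'   gene and symptom counts.
#' @export
table1_fixture <- function(n_nonrare = 30, seed = 1L) {
  panel <- study_panel()
  base <- generate_graph(generator_config(
    n_rare = 1, n_nonrare = n_nonrare,
    vocab_sizes = c(genes = 300, symptoms = 400, proteins = 300,
                    pathways = 80, variants = 120),
    n_drugs = 30, n_planted = 0, background_overlap = 0.1,
    planted_overlap = 0.9, seed = seed))$graph

  # drop the placeholder rare disease, then install the 13-disease panel
  keep <- !base$diseases$is_rare
  diseases <- base$diseases[keep, ]
  edges <- base$edges
  for (nm in paste0("disease_", NODE_ROLES)) {
    edges[[nm]] <- edges[[nm]][edges[[nm]]$disease_id %in% diseases$id, ]
  }
  edges$gda <- edges$gda[edges$gda$disease_id %in% diseases$id, ]

  diseases <- dplyr::bind_rows(
    tibble::tibble(id = panel$cui, name = panel$disease, is_rare = TRUE,
                   prevalence_class = "<1/1000000",
                   prevalence_geography = "Worldwide"),
    diseases)

  gene_vocab <- base$nodes$id[base$nodes$role == "gene"]
  sym_vocab <- base$nodes$id[base$nodes$role == "symptom"]
  dg <- ds <- list()
  withr::with_seed(substream_seed(seed, "panel"), {
    for (i in seq_len(nrow(panel))) {
      dg[[i]] <- tibble::tibble(disease_id = panel$cui[i],
                                feature_id = sample(gene_vocab, panel$n_genes[i]))
      ds[[i]] <- tibble::tibble(disease_id = panel$cui[i],
                                feature_id = sample(sym_vocab, panel$n_symptoms[i]))
    }
  })
  edges$disease_gene <- dplyr::bind_rows(edges$disease_gene, dplyr::bind_rows(dg))
  edges$disease_symptom <- dplyr::bind_rows(edges$disease_symptom, dplyr::bind_rows(ds))

  knowledge_graph(diseases, base$drugs, base$nodes, edges)
}

#' The 13-disease study panel: identifiers and profile sizes
#'
#' @return Tibble with columns `cui`, `disease`, `n_genes`, `n_symptoms`.
#' @export
study_panel <- function() {
  tibble::tribble(
    ~cui, ~disease, ~n_genes, ~n_symptoms,
    "C0011195", "Dejerine-Sottas syndrome", 31L, 10L,
    "C0023944", "Locked-In Syndrome", 1L, 17L,
    "C0024054", "Lown-Ganong-Levine syndrome", 1L, 6L,
    "C0024901", "Diffuse cutaneous mastocytosis", 1L, 237L,
    "C0027877", "Congenital neuronal ceroid lipofuscinosis", 38L, 52L,
    "C0036391", "Schwartz-Jampel syndrome", 23L, 5L,
    "C0265202", "Seckel syndrome", 15L, 4L,
    "C0268059", "Neonatal hemochromatosis", 1L, 43L,
    "C0549463", "X-Linked Lymphoproliferative Disorder", 11L, 1L,
    "C0751337", "X-Linked Emery-Dreifuss Muscular Dystrophy", 44L, 32L,
    "C0869083", "Dahlberg-Borer-Newcomer syndrome", 12L, 2L,
    "C1852146", "Vibratory urticaria", 1L, 11L,
    "C0796280", "Acromegaloid facial appearance syndrome", 1L, 90L
  )
}

#' Literature-validation bookkeeping fixture
#'
#' Per-disease candidate/validation counts for the 12 diseases of the study
#' panel that were carried through literature validation (the
#' Lown-Ganong-Levine row is excluded as its single-approach result set was
#' discarded): number of computational candidates, number checked against
#' literature and clinical trials, and the therapeutic/toxic split of the
#' checked drugs.
#'
#' @return Tibble with columns `disease_id`, `disease`, `computational`,
#'   `checked`, `therapeutic`, `toxic`.
#' @export
checked_drugs_fixture <- function() {
  tibble::tribble(
    ~disease_id, ~disease, ~computational, ~checked, ~therapeutic, ~toxic,
    "C0011195", "Dejerine-Sottas syndrome", 2L, 2L, 1L, 1L,
    "C0023944", "Locked-In Syndrome", 80L, 11L, 2L, 9L,
    "C0024901", "Diffuse cutaneous mastocytosis", 4L, 4L, 3L, 1L,
    "C0027877", "Congenital neuronal ceroid lipofuscinosis", 48L, 7L, 5L, 2L,
    "C0036391", "Schwartz-Jampel syndrome", 14L, 1L, 1L, 0L,
    "C0265202", "Seckel syndrome", 2L, 1L, 0L, 1L,
    "C0268059", "Neonatal hemochromatosis", 91L, 8L, 3L, 5L,
    "C0549463", "X-Linked Lymphoproliferative Disorder", 1L, 0L, 0L, 0L,
    "C0751337", "X-Linked Emery-Dreifuss Muscular Dystrophy", 126L, 15L, 11L, 4L,
    "C0869083", "Dahlberg-Borer-Newcomer syndrome", 8L, 8L, 0L, 8L,
    "C1852146", "Vibratory urticaria", 2L, 2L, 0L, 2L,
    "C0796280", "Acromegaloid facial appearance syndrome", 2L, 1L, 1L, 0L
  )
}
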