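# Fixture graphs built in code, shared across test files.

# Small generator config for fast randomised suites.
tiny_config <- function(seed, n_planted = 1, planted_overlap = 0.9,
                        background_overlap = 0.1, n_rare = 2, n_nonrare = 8,
                        n_drugs = 6, confederates = 3) {
  generator_config(
    n_rare = n_rare, n_nonrare = n_nonrare, n_drugs = n_drugs,
    vocab_sizes = c(genes = 12, symptoms = 10, proteins = 12, pathways = 6,
                    variants = 8),
    profile_size_ranges = list(genes = c(1, 4), symptoms = c(2, 4),
                               proteins = c(1, 3), pathways = c(1, 2),
                               variants = c(1, 3)),
    n_planted = n_planted, planted_overlap = planted_overlap,
    background_overlap = background_overlap,
    confederates_per_plant = confederates, seed = seed)
}

# Strong-signal config used in planted-recovery checks: confederate profiles
# duplicate the rare disease's, no background sharing mechanism.
strong_config <- function(seed, planted_overlap = 1.0) {
  generator_config(
    n_rare = 3, n_nonrare = 30, n_drugs = 15,
    vocab_sizes = c(genes = 80, symptoms = 60, proteins = 80, pathways = 30,
                    variants = 40),
    profile_size_ranges = list(genes = c(2, 6), symptoms = c(2, 6),
                               proteins = c(1, 4), pathways = c(1, 3),
                               variants = c(1, 3)),
    n_planted = 2, planted_overlap = planted_overlap,
    background_overlap = 0, confederates_per_plant = 5, seed = seed)
}

# Minimal direct-approach chain: rare disease R1 -gene-> G1 -encodes-> P1,
# drug D1 targets P1; plus a geneless rare disease R2 and one background
# non-rare disease.
toy_direct_graph <- function() {
  knowledge_graph(
    diseases = data.frame(
      id = c("R1", "R2", "N1"), name = c("rare one", "rare two", "common one"),
      is_rare = c(TRUE, TRUE, FALSE), prevalence_class = "<1/1000000",
      prevalence_geography = "Worldwide"),
    drugs = data.frame(id = "D1", name = "drug one", atc_codes = "C07AG02"),
    nodes = data.frame(id = c("G1", "P1", "S1"),
                       role = c("gene", "protein", "symptom")),
    edges = list(
      disease_gene = data.frame(disease_id = "R1", feature_id = "G1"),
      disease_symptom = data.frame(disease_id = c("R1", "R2"),
                                   feature_id = c("S1", "S1")),
      gene_protein = data.frame(gene_id = "G1", protein_id = "P1"),
      drug_target = data.frame(drug_id = "D1", node_id = "P1")))
}

# Hand-built graph exercising all six traversal paths with one drug per
# path; hand enumeration: P1={DA} P2={DB} P3={DC} P4={DD} P5={DE} P6={DF}.
toy_paths_graph <- function() {
  knowledge_graph(
    diseases = data.frame(
      id = c("RD", "N1", "N2"), name = c("rare", "sym sharer", "gene sharer"),
      is_rare = c(TRUE, FALSE, FALSE), prevalence_class = "unknown",
      prevalence_geography = "Worldwide"),
    drugs = data.frame(id = c("DA", "DB", "DC", "DD", "DE", "DF"),
                       name = paste("drug", 1:6), atc_codes = ""),
    nodes = data.frame(
      id = c("S1", "S2", "G1", "G2", "P1", "P2", "P3"),
      role = c("symptom", "symptom", "gene", "gene", "protein", "protein", "protein")),
    edges = list(
      disease_symptom = data.frame(disease_id = c("RD", "RD", "N1"),
                                   feature_id = c("S1", "S2", "S1")),
      disease_gene = data.frame(disease_id = c("RD", "N1", "N2"),
                                feature_id = c("G1", "G2", "G1")),
      gene_protein = data.frame(gene_id = c("G1", "G2"), protein_id = c("P1", "P2")),
      ppi = data.frame(protein_a = "P1", protein_b = "P3"),
      drug_indication = data.frame(drug_id = c("DA", "DB", "DD"),
                                   node_id = c("S1", "N1", "N2")),
      drug_target = data.frame(drug_id = c("DC", "DE", "DF"),
                               node_id = c("P2", "P1", "P3"))))
}

# Two-feature triples toy: neighbour NA shares a gene with R, neighbour NB a
# symptom; NA is indicated for {d1, d2}, NB for {d2}. With share_min = 1 the
# gene group is {d1, d2}, the symptom group {d2}, so the cross-feature
# intersection is {d2}.
toy_triples_graph <- function() {
  knowledge_graph(
    diseases = data.frame(
      id = c("R", "NA1", "NB1"), name = c("rare", "a", "b"),
      is_rare = c(TRUE, FALSE, FALSE), prevalence_class = "unknown",
      prevalence_geography = "Worldwide"),
    drugs = data.frame(id = c("d1", "d2"), name = c("one", "two"), atc_codes = ""),
    nodes = data.frame(id = c("G1", "S1"), role = c("gene", "symptom")),
    edges = list(
      disease_gene = data.frame(disease_id = c("R", "NA1"), feature_id = "G1"),
      disease_symptom = data.frame(disease_id = c("R", "NB1"), feature_id = "S1"),
      drug_indication = data.frame(drug_id = c("d1", "d2", "d2"),
                                   node_id = c("NA1", "NA1", "NB1"))))
}

expect_same_set <- function(a, b) {
  testthat::expect_identical(sort(unique(a)), sort(unique(b)))
}
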