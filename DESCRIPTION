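Package: raredr
Title: Drug Repositioning for Rare Diseases over Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature-based drug-repositioning analysis for rare diseases over a
    disease-centric biomedical knowledge graph. Provides an edge-list knowledge
    graph model with referential-integrity validation, a synthetic graph
    generator with planted repositioning signal, Orphanet-style prevalence
    filtering of candidate diseases, per-feature Jaccard disease similarity with
    deterministic top-k rankings, four candidate-generation approaches (triples,
    target-constrained triples, direct gene-target, and six-path traversal) with
    set-intersection combiners, and downstream validation statistics
    (literature-validation bookkeeping, ATC level-1 composition, Welch phenotypic
    similarity test, Mann-Whitney gene-disease association test), orchestrated by
    a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
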