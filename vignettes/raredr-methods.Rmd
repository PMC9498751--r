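---
title: "Methods: feature-based drug repositioning for rare diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based drug repositioning for rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raredr)
```

## The problem and the data model

Most rare diseases lack an approved treatment, and de-novo development is
rarely economical at their prevalence. Drug repositioning asks whether a drug
already indicated for some common disease could plausibly treat a rare one.
`raredr` implements a knowledge-graph formulation of that question: diseases,
drugs, and five kinds of biological features (genes, symptoms, proteins,
pathways, variants) are nodes; typed association edges connect diseases to
their features, drugs to their indications (disease or symptom concepts) and
protein targets, genes to the proteins they encode, proteins to their
interaction partners, and gene-disease pairs to association scores (GDA,
with DSI and DPI indices, each in $[0,1]$).

The container is an S3 list of tidy tables (`knowledge_graph()`), persisted
as a ten-file TSV set so fixtures stay hand-editable and diffable.
Symptom concepts share an identifier space with diseases, which lets a drug
indication point at either; a node-role table disambiguates. Construction
validates referential integrity, the closed Orphanet-style prevalence
vocabulary (the three undocumented variants collapse to `"unknown"`), and
ATC code shape. Protein-interaction pairs are stored order-independently,
and duplicate edge rows are dropped with a warning, since all edge sets are
sets.

## Disease similarity

For two diseases with feature sets $A$ and $B$ of one kind,

$$J(A, B) = \frac{|A \cap B|}{|A \cup B|},$$

with $J = 0$ when both sets are empty. Each rare disease is compared against
every non-rare disease per feature kind, and the top $k = 5$ neighbours
(the study default; `k` is a parameter) are kept with a deterministic
ordering contract: non-increasing score, ties broken by ascending disease
id, zero-score neighbours excluded. Ties crossing the $k$-th rank are
truncated after the id tie-break rather than extended — padding with
zero-score or post-tie entries would make "top 5" arbitrary — and a message
notes when truncation was triggered.

## Candidate generation

Four approaches produce per-disease candidate drug sets:

1. **Triples** — per feature kind, collect the drugs indicated for the top-5
   neighbours and keep those linked to at least `share_min` of them; then
   intersect the non-empty per-feature groups. "Shared among the top-5
   neighbours" is operationalised as `share_min = 2` by default (the minimal
   reading of *shared*); raising it to `k` gives a strict-intersection
   reading. Because the per-feature union is another defensible reading of
   the triples count, the run summary reports both the intersection and the
   union cardinalities.
2. **Target-constrained triples** — as above, but a neighbour's drug only
   counts if the rare disease and that neighbour share a gene encoding one
   of the drug's target proteins.
3. **Direct** — drugs targeting a protein encoded by one of the rare
   disease's own genes.
4. **Paths** — six traversals (symptom-indication, symptom-sharing disease
   indication, symptom-sharing disease gene-target, gene-sharing disease
   indication, own gene-protein-target, and interaction-partner target);
   the non-empty path sets are intersected.

Two combiners intersect the non-empty approach sets: `all` over all four,
`ttddrp` without the plain triples set (the most generalist approach). A
lone non-empty set therefore passes through unchanged, and disjoint
non-empty sets give an empty combination. Empty member sets are excluded
from every intersection, by analogy with the explicit non-empty-set rule of
the combiners; a strict reading (any empty group voiding the result) can be
recovered by filtering on the reported per-group sets.

Design choices where the procedure was genuinely open:

* Intermediate diseases in the symptom- and gene-sharing paths exclude the
  rare disease itself and are restricted to non-rare diseases by default
  (`restrict_nonrare`), since candidate sources are meant to be the
  better-annotated common diseases.
* Drugs already indicated for the rare disease are flagged as known
  treatments and removed from candidate lists (`exclude_known`):
  repositioning proposes *new* indications.
* All drug sets are sorted by id, making every output deterministic.

## Disease selection

`select_diseases()` filters a disease universe by rarity, graph presence
(at least one feature edge), absence of an existing indication edge,
availability of both genes and symptoms, prevalence geography (default
whitelist `"Worldwide"`), prevalence class (default `"<1/1000000"`, the
most extreme rarity class), and optional gene/symptom ceilings. The ceilings
ship without a default because no principled threshold exists; they encode a
computational-cost preference, not biology. Filters commute, so the survivor
set is order-independent; only the attrition report reflects the fixed stage
order.

## Downstream statistics

**Validation bookkeeping.** Literature validation of candidates is a manual
step; the package implements its arithmetic. Per disease,
`checked = therapeutic + toxic` and `checked <= computational` are enforced
as load-time invariants. The computational candidate set backing the counts
is the `ttddrp` combination when non-empty and the `all` combination
otherwise — the convention that reproduces the published per-disease counts
of the reference panel, where one disease's `ttddrp` set is empty while its
`all` set is not. Because "success" admits two readings, both fractions are
reported: diseases with at least one therapeutic drug, and diseases with any
literature evidence at all.

**ATC composition.** Candidates are classified by the first (anatomical)
level of their ATC codes; a drug spanning several first-level classes counts
once per class, and drugs without a code are reported as `unclassified`, so
the histogram total can exceed the number of drugs.

**Phenotypic similarity.** Hypothesis pairs (rare disease, non-rare disease
of the original indication) must share a gene encoding a target of the
corresponding drug — violating pairs are a validation error, not silently
dropped. Symptom-set Jaccard scores of the hypothesis pairs are compared to
the background of all rare/non-rare pairs with a two-sided Welch $t$ test
(unequal variances; sidedness is not assumed, and the direction is reported
separately so reversed findings stay visible). With a singleton or fully
constant sample the $p$-value is undefined and reported as `NA` while the
group means are still returned.

**Gene-disease association strength.** Per rare disease, the GDA scores of
its hypothesis genes are compared against all GDA scores in the graph
(including the hypothesis records, matching the "all diseases and their
genes" background definition; a leave-out mode exists) with a two-sided
Mann-Whitney U test, since GDA scores are bounded and far from normal.
All-tied degenerate comparisons return $p = 1$. $p$-values are reported raw,
per disease, with no multiple-testing correction — a deliberate mirror of
per-disease reporting practice, and a documented limitation for wider
screens.

## The synthetic generator

Real snapshots of a production disease knowledge base are neither
redistributable nor desk-scale, so every stage is exercised on generated
graphs with planted ground truth.

*Background*: each disease draws a profile size per feature kind uniformly
from `profile_size_ranges` (defaults motivated by the gene/symptom set sizes
of well-annotated rare diseases, such as 1-44 genes), then samples features
with a shared-pool mechanism — with probability `background_overlap` a draw
comes from a small hub sub-vocabulary (`hub_fraction` of the vocabulary).
This keeps background Jaccard small but non-zero, which matters: the Welch
and Mann-Whitney background distributions must be non-degenerate for the
calibration checks to mean anything. Background drugs receive random ATC
codes, 1-3 protein targets, and indications to random non-rare diseases and
symptoms, so all six paths have non-trivial traversals. Every gene encodes
one protein (round-robin), guaranteeing gene-protein chains exist.

*Planted signal*: each plant selects a rare disease, five (configurable)
non-rare confederates, and a dedicated drug. A shared gene is attached to
the rare disease and every confederate; the drug targets the protein that
gene encodes, is indicated for every confederate, for one symptom of the
rare disease, and one interaction edge links the target protein to another
protein encoded by the rare disease's genes. This makes the planted drug
recoverable by the direct approach by construction and by all six paths;
confederates copy a fraction `planted_overlap` of the rare disease's
features (replacing their own up to the original profile size), so at
`planted_overlap = 1` their profiles coincide with the rare disease's and
they fill every top-5 ranking. `planted_overlap` must exceed
`background_overlap`, otherwise the signal is undetectable and the
configuration is rejected. GDA scores of planted rare diseases' gene
associations draw from `Beta(8, 2)` and all others from `Beta(2, 8)` —
the scores are only bounded to $[0,1]$ by their definition, so the shapes
are configuration, chosen to give a strong, clearly separated signal;
planted rare diseases are guaranteed at least three genes so the per-disease
Mann-Whitney hypothesis sample is never degenerate.

One global seed feeds deterministic per-component substreams, so adding a
generator component does not perturb the draws of the others; identical
configurations produce byte-identical saved file sets.

What the generator does *not* emulate: the degree distributions, annotation
biases, and cross-source inconsistencies of a real knowledge base, ontology
structure among symptoms, or correlated pleiotropy between feature kinds.
Passing tests therefore demonstrate correctness of the algorithms and
calibration of the statistics under controllable conditions — not that the
pipeline's candidates from any particular real snapshot are clinically
meaningful.

## Verification and problem sizes

The test suite cross-checks every approach against independent brute-force
chain enumerations on 50 random small graphs (about 16 disease/drug nodes
each), checks planted-drug recovery at maximal overlap across 20 seeds with
recovery monotone in `planted_overlap` over $\{1.0, 0.8, 0.6, 0.4\}$,
calibrates the Welch stage with a 1000-replicate null resampling simulation
(hypothesis $n = 100$ against background $n = 400$ drawn from the empirical
score pool of a 128-disease graph, sizes chosen so the central limit
approximation is comfortably in force for zero-inflated Jaccard scores),
and measures Mann-Whitney power over 15 generated graphs with three plants
each. Round-trip, referential-integrity, and determinism properties run on
batches of 10-20 random graphs. Welch and Mann-Whitney code paths are
pinned to reference $p$-values computed once with an independent
implementation and frozen into the tests. These sizes keep the default
suite under a minute while leaving every property with enough replicates to
be informative.

## End-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(n_rare = 5, n_nonrare = 60, n_planted = 2,
                               seed = 11),
  criteria = selection_criteria(exclude_with_treatment = FALSE,
                                geography_whitelist = NULL,
                                prevalence_whitelist = NULL),
  seed = 11)
res <- run_pipeline(cfg, "report")
res$repositioning$summary
```

The bundle contains the selection attrition, per-feature similarity tables,
the per-approach candidate summary, candidate membership lists, the two
hypothesis tests, the ATC histogram, and a manifest of md5 digests. Output
paths never enter the bundle, so identical configuration and seed give
byte-identical bundles wherever they are written.

## Known limitations

* Jaccard over raw identifier sets ignores ontology structure; two diseases
  annotated at different granularity of the same phenotype score as
  dissimilar.
* The validation step (literature/clinical-trial checking) remains manual;
  the package only enforces its bookkeeping.
* Raw per-disease $p$-values; apply `p.adjust` before interpreting many
  diseases jointly.
* The generator's planted signal is symmetric across feature kinds, which
  is kinder to the triples approach than real data would be.
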