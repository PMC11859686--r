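---
title: "Two-branch screening of formula corpora: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-branch screening of formula corpora: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ayurnet)
```

This vignette is the package's own account of its methods: the model behind
each stage, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the choices we made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The data model

The unit of analysis is a *formula*: a set of medicinal plants drawn from a
fixed vocabulary, coded as a binary row of an incidence matrix, with a binary
class label (1 = the formula is indicated for conditions of bacterial
origin). `formula_dataset()` enforces the invariants every stage relies on:
0/1 entries, a label for every formula, unique plant and formula identifiers,
and no empty formulae. Nothing in the package models dosage, preparation, or
herb–herb synergy; a plant is either in a formula or it is not.

## Network branch

### Distance and thresholding

`build_network()` connects two formulae when their Minkowski distance
d_p = (Σ|xᵢ−yᵢ|^p)^(1/p) is **strictly** below a threshold. Defaults are
p = 2 and threshold 1.5. On binary vectors d_p = H^(1/p) with H the Hamming
distance, so the default connects exactly the pairs differing in at most two
plants (√2 ≈ 1.414 < 1.5 < √3 ≈ 1.732). Strictness matters only on the
measure-zero boundary but is pinned down by tests. `p` is exposed because
the distance family, not one order, is the modelling choice; the p = 1
network at threshold t coincides with the p = 2 network at √t on binary
data, which the tests verify.

Edges carry unit weight by default. In the unweighted regime the seed rule
of the clustering (highest incident weight) degenerates to highest remaining
degree, which is the intended default behaviour. An optional
`edge_weighting = "similarity"` sets weight = threshold − distance for
exploring weighted seeding; nothing downstream requires it.

### Overlapping clustering

`run_dpcluso()` implements DPClusO-style overlapping density clustering.
Definitions, for a member set N of the *remaining* graph (see below):

* density(N) = 2|E_in| / (|N|(|N|−1)), 1 for singletons by convention;
* cluster property of an outside node k: CP(k, N) = |E_k→N| / (density(N)·|N|);
* overlap of a candidate C with an accepted cluster A: |C∩A| / |C|.

Defaults: density ≥ 0.5, CP ≥ 0.4, overlap ≤ 0.1, minimum size 2.

The loop: pick the seed with the largest total remaining edge weight (ties:
remaining degree, then lexicographic node id; nodes already clustered are
deferred while unclustered seeds exist); grow by scanning cluster neighbours
in priority order (connection weight to members, degree, id) and admitting
the first whose admission keeps the density floor and whose CP clears the
gate; accept the grown cluster if its overlap with every accepted cluster is
within the ceiling, deleting all remaining edges inside it; on rejection the
seed is ineligible for the rest of the round. After the loop, every
never-clustered node is emitted as a singleton, so coverage (every node in
at least one cluster) holds exactly.

Two points were genuinely open and are our stipulations:

* **All quantities are computed on the remaining graph** (edges inside
  accepted clusters are deleted as covered). This is what makes progress
  provable: a seed incident to any remaining edge always admits its first
  neighbour (density 1, CP 1), so every accepted cluster deletes at least
  one edge.
* **Termination guard.** A full round can end with only overlap-rejected
  clusters (e.g. two 4-cliques sharing a node at the default ceiling: the
  second clique always grows back to the shared node and is rejected). The
  guard deletes the internal remaining edges of that round's rejected
  candidates before the next round, so the edge count strictly decreases and
  termination is guaranteed. On the two-clique example the result under
  defaults is the first clique plus singletons; at overlap ≤ 0.25 both
  cliques are accepted and share the common node. Both traces are frozen in
  tests.

All tie-breaks are total orders, so the clustering is deterministic,
including cluster order — asserted by tests on random graphs.

### Voting and candidate extraction

`cluster_score()` is the exact fraction of cluster members in class 1.
`select_dominant()` keeps clusters with score **strictly** above
`min_score` (default 0.5 — the natural majority-vote reading) and at least
`min_size = 2` members. `extract_network_candidates()` supports each plant
by the number of distinct formulae, within the union of dominant clusters,
containing it, and keeps plants with support ≥ 2: one co-occurrence is not
evidence of recurrence.

## ML branch

`compare_models()` evaluates seven classifiers under three preprocessing
variants (variance filtering; SMOTE; both) by stratified cross-validation
(default 5 folds, 1 repeat). PCA (components explaining ≥ 95% of variance,
or a fixed count such as 146 ≈ half the default vocabulary) is applied in
every variant, since dimensionality reduction is part of the modelling
pipeline this package mirrors. The reported dispersion is the standard
deviation across fold accuracies.

**Leakage.** By default every preprocessing step — variance filter, PCA,
SMOTE — is fitted inside the training folds only; synthetic minority rows
never appear in evaluation folds. `leakage_safe = FALSE` reproduces the
historically common (and optimistically biased) protocol of balancing the
full dataset before cross-validation; it exists for comparability, not use.

**SMOTE** (`balance_smote()`) generates minority rows as convex combinations
x_i + u(x_j − x_i), u ~ U(0,1), of a minority sample and one of its k = 5
nearest minority neighbours. Classes end exactly balanced; original rows are
preserved verbatim. No installed package provides SMOTE, so it is
implemented here and pinned by geometric tests.

**Tuning.** `tune_rf()` grid-searches the forest (trees, depth, minimum
leaf, minimum split; default grid 50/100 × 10/15 × 1/5 × 2/5) under the
filtering + SMOTE variant, breaking ties towards the smaller model (fewer
trees, then shallower).

**Permutation importance.** `importance_ranking()` refits the forest on the
variance-filtered *plant-level binary matrix* — not on principal components,
because weights must map back to plant names — and scores each plant by the
mean accuracy drop over 5 permutations of its column. Two deliberate
choices:

* The importance fit enlarges the tuned forest to at least
  `importance_trees = 500` trees. Ensemble size is not a complexity
  parameter (more trees cannot overfit); small ensembles simply make
  permutation importances noise-dominated, which a feature-*ranking* stage
  cannot afford. Depth, leaf and split remain the tuned values.
* Importance is evaluated on the fitting data. This inflates absolute
  weights for deep forests but preserves the ranking the candidate cut uses;
  the null behaviour (weights ≈ 0 for label-independent plants) is pinned by
  tests.

A classification forest is used even where comparable workflows name a
regression forest on the 0/1 label; `mode = "regressor"` reproduces that
variant (predictions thresholded at 0.5) for comparison. Correlated plant
columns split importance credit — a duplicated decisive column can halve
each copy's weight — so the candidate threshold is applied to a ranking in
which jointly-informative duplicates are a known caveat (tests pin the
joint-mass behaviour).

`select_ml_candidates()` keeps plants with weight **strictly** above 0.01;
`threshold_sensitivity()` sweeps 0.005–0.02 and reports the (non-increasing)
candidate counts, so a knife-edge selection is visible.

## Overlap and name normalization

Compiled plant tables disagree on spellings. `name_normalizer()` folds case
and whitespace to "Genus species" form and applies an explicit typo/synonym
map (shipped in `extdata/plant_synonyms.csv`); normalization is idempotent
by construction and by property test. `intersect_candidates()` reports the
canonical-name intersection of the two branches with both supports;
duplicated names inside a verbatim input collapse to their maximum support.
Given a reference list, members outside it are *flagged* (`in_reference =
FALSE`), never dropped: on the bundled tables the strict intersection has 19
members, of which 17 match the published final list — the audit flag
surfaces the two extras rather than silently reconciling them.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the study conditions:

* **Shape** 285 × 293 and class-1 fraction 0.35 (a minority antibiotic
  class, so SMOTE is exercised).
* **Heavy-tailed plant frequencies**: sampling weight r^(−0.5) for frequency
  rank r. Against the bundled frequency table this predicts a top-plant
  count of ≈117/285 (printed: 102) and reproduces the printed rank-40/rank-1
  ratio (18/102 implies an exponent ≈ 0.47).
* **Per-formula sizes** uniform on 3–25.
* **Recipe families** (`variant_rate = 0.35`): a formula is, with this
  probability, a single-edit variant (swap/add/remove of one ingredient) of
  an earlier formula, inheriting its class label. This field exists because
  independent sampling yields an essentially empty network at the default
  distance threshold (a 285-formula draw produced one edge): what the strict
  threshold detects in real corpora is precisely the base-prescription
  families, where variants sit at Hamming distance 1–2 from their parent.
* **Planted signal**: 10 signal plants whose sampling weights are multiplied
  by 8 inside class-1 formulae. Signal enters through the sampling weights,
  not post-hoc insertion, so per-formula sizes stay in range.

What the generator does **not** emulate: real co-prescription structure
(synergy, dosage, preparation), plant-name noise (all synthetic names are
already canonical), or any semantics of the class label beyond its
statistical coupling to composition. Passing tests therefore demonstrate
that the pipeline recovers *this kind* of planted structure, not that any
particular real plant is antibacterial.

Two derived experimental designs in the tests deserve a note:

* **Recovery study**: 400 formulae, 10 signal plants, enrichment 8, five
  seeds; both branches must recover a median of ≥ 8/10 planted plants and
  the overlap must be majority-planted.
* **Null study**: enrichment 1 *and* `variant_rate = 0` *and* balanced
  classes. All three are necessary for a clean null: label-inheriting
  families make composition genuinely predictive of the label even without
  signal plants, and 0.5 is chance accuracy only for balanced labels (a
  majority-class predictor scores the majority rate regardless of signal).
  Under this null all model accuracies must sit within 3 SD of 0.5, the
  chi-square independence test on planted plants must be non-significant
  (the test is calibrated because independent sampling makes formulae
  exchangeable), and planted-vs-other importances must be
  indistinguishable.

## Numerical and engineering choices

* All threshold comparisons ("below", "greater than") are strict, matching
  their narrative readings; boundary behaviour is tested.
* `association_audit()` applies the Haldane–Anscombe 0.5 correction to all
  cells of every 2×2 table, not only degenerate ones: a uniformly corrected
  estimator is finite everywhere and comparable across plants.
* Random-forest prediction is explicitly seeded everywhere: with an even
  tree count a classification vote can tie, and the tie is otherwise broken
  with an ambient RNG draw, which made repeated pipeline runs
  data-dependently nondeterministic until pinned.
* `run_pipeline()` expands one global seed into fixed per-stage substreams,
  so a stage can be re-run reproducibly in isolation; artifacts are
  delimited text with MD5 checksums in the manifest, and identical
  config + seed gives identical checksums (tested).
* Problem sizes in the test suite — corpora of 50–400 formulae, 200 random
  graphs of ≤ 30 nodes for the clustering properties, five seeds for the
  recovery study — were chosen so the full suite and the acceptance script
  each complete in minutes on one CPU while keeping the statistical checks
  meaningful.
* The package's interface is its exported functions plus
  `scripts/acceptance.R`; an analysis package of this kind is driven from R
  scripts, so no shell entry point is shipped.

## Known limitations

* The overlap-acceptance rule of the clustering (reject when
  |C∩A|/|C| exceeds the ceiling) is one of several defensible readings of
  overlap control; it is isolated behind `overlap_fraction()` so
  alternatives can be swapped in.
* Permutation importance on correlated binary columns divides credit;
  near-duplicate ingredients should be merged (the reader of
  `read_formula_table()` already ORs columns that normalize identically).
* The logistic regression is fitted unpenalized on PC scores; with many
  components and few samples it can sit near separation, and its fold
  accuracies are accordingly more variable than the regularized learners.
* Dominance uses a fixed majority threshold, not an enrichment test with
  multiplicity control; with many small clusters some dominant clusters are
  expected by chance, which is why candidate support is counted over
  formulae, not clusters.
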