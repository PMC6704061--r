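---
title: "Building hERG classifiers with NSGA-II descriptor selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building hERG classifiers with NSGA-II descriptor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergsel)
```

## The problem

hERG (the human Ether-a-go-go Related Gene potassium channel) binds
structurally diverse small molecules; blocking it prolongs the cardiac QT
interval, so an *in silico* hERG inhibition flag is a standard early
triage filter in drug discovery. Useful training data are scattered
across databases with incompatible assay formats — dose-response IC50
values and single-concentration percent-inhibition readings — and with
contradictory reports for the same compound. This package implements the
complete model-building recipe from raw per-source assay records to a
deployed classifier with a reliability estimate per prediction.

## Curation model

Each assay record is labeled independently: *inhibitor* when IC50 ≤ 10 μM
or percent inhibition at 10 μM ≥ 50 (both boundaries inclusive on the
inhibitor side), else *inactive*. Per compound:

* exact duplicate records (same key, reference, type and value) collapse
  to one — the same measurement reported through two databases is one
  observation, not two;
* if any IC50 records exist, *only* IC50 records vote. "Prioritized" is
  read as total priority, not down-weighting, because no weighting scheme
  is defined anywhere; this is the simplest rule consistent with the
  wording and it makes resolution order-invariant;
* the majority class wins only when its vote fraction is **strictly**
  greater than 2/3. A 2-of-3 split is therefore *excluded*. We read
  "more than two thirds" literally; the alternative (≥) would silently
  keep maximally ambiguous 2-of-3 compounds.

Compounds with a single report resolve to that report's class (fraction
1 > 2/3). Records with non-finite values, non-positive IC50s, unknown
measurement types, or a missing entry in a supplied units column are
rejected with a diagnostic, never guessed.

The train/test split is stratified by class with per-class
`floor(n × fraction)` test counts; only stratification and seed
reproducibility are promised (historically printed splits of this kind
are off-by-one from exact 70/30 and cannot be reproduced bit-for-bit).

## Descriptor preprocessing

Three ordered filters, each logged with a reason: explicit blacklist,
zero variance, then greedy correlation pruning. Pairs are visited in
input column order and the **later** column of an offending pair
(|Pearson r| > 0.85) is dropped. The order rule is a convention — any
deterministic tie-break yields a valid maximal set — chosen so that the
surviving set is stable under appending columns, which also gives the
monotonicity property the tests assert. Absolute correlation is the
default because a strongly anti-correlated descriptor is just as
redundant for an RBF kernel; `use_abs = FALSE` restores the signed
reading.

The majority class is trimmed to a class-balanced selection set by
clustering fingerprints under Tanimoto distance and keeping one
representative per cluster. The clustering algorithm is deliberately
simple and exactly reproducible: max-min (sphere-exclusion) seeding from
a seeded random start, nearest-seed assignment, then medoid refinement.
A medoid — unlike a centroid — is guaranteed to be a real compound,
which is the point of the trim.

## The SVM and its objective

The classifier is a soft-margin RBF-kernel SVM. Because no SVM solver is
available as a dependency in the target environment, the dual problem is
solved inside the package by SMO with maximal-violating-pair working-set
selection (the textbook C-SVC algorithm), with a dense precomputed Gram
matrix (memory O(n²), guarded at n = 8192 — ample for the balanced
selection sets this stage is designed for). The unit tests check the SMO
solution against an independent quadratic-programming solve of the same
dual (`quadprog`) to 1e-3 on the dual variables.

Class imbalance (~1:28 after curation at full scale) is handled by the
class-weight heuristic: the minority class penalty is
`C × N_majority/N_minority`, recomputed from each training fold. During
subset search the hyperparameters are frozen at `C = 1`,
`γ = 1/nx` (`nx` = number of active features, fingerprint bits included
when combined). The source description of these defaults is internally
contradictory (its "respectively" maps 1.0 to gamma and 1.0/nx to C,
while its own grid search scales gamma and not C by 1/nx); we follow the
grid-search convention, which also matches the common solver default,
and both assignments remain reachable through `svm_config()`.

The selection objective is the mean Cohen's kappa of stratified 5-fold
cross-validation. Folds are stratified (unstratified folds are unstable
at 1:28), drawn once per run and shared across all masks and all grid
cells, making every comparison paired. Kappa rather than accuracy: with
97 % inactives, accuracy saturates at 0.97 for the trivial model while
kappa stays near 0.

## NSGA-II over descriptor masks

Individuals are fixed-length bit masks; objectives are (kappa CV,
subset size), internally minimized as (−kappa, n). The loop is standard
NSGA-II: fast non-dominated sort, crowding distance with infinite
boundary distance, binary tournament on (rank, crowding), elitist
environmental selection on the merged parent+offspring population.
Operator choices left open by the published parameterization:

* **uniform crossover** per bit (rate 0.6) — descriptors are unordered,
  so positional crossover has no meaning;
* **initialization** with per-bit on-probability 0.1 — a sparse start
  matches the small-subset objective and avoids evaluating
  full-width masks;
* **empty-mask repair** by switching one uniformly chosen bit on — an
  empty subset is unevaluable;
* evaluation **cache** keyed by mask, so re-visited subsets are free and
  determinism is testable through an evaluator call counter;
* the per-generation **archive** stores each generation's level-1 front;
  the **dominance ratio** (fraction of the previous front dominated by
  the current front) is the convergence diagnostic — it falls toward 0
  as the front stops moving.

Asymmetric mutation (0.02 off→on, 0.2 on→off) biases the walk toward
small subsets, matching the size objective.

## Candidate recombination and final models

Descriptor-only selection runs on the balanced trimmed set; the final
front's descriptor sets are then each combined with the full fingerprint
bit matrix and re-scored by kappa CV on the *full, imbalanced* training
rows with class weights — mirroring the two-dataset usage that motivated
the trim. Fresh folds, fixed once for the whole stage, are used here:
the selection-stage folds belong to a different row set, so they cannot
be reused, and per-candidate fold redraws would unpair the comparison.
The fingerprint-only baseline (empty descriptor set) is always scored as
the reference.

Candidates are thinned in two steps: the best per right-closed size bin
(`(0,10], (10,20], …`; ties to the smaller set), then a monotone scan
dropping any candidate whose kappa does not strictly exceed every
retained smaller candidate. The result is a strict staircase in both
size and kappa. The final candidate is grid-searched
(C ∈ {0.5, 1, 2}, γ ∈ {0.5, 1, 2}/nx, ties to smaller C then smaller γ)
and refit on all training rows; test rows are touched exactly once, by
the final evaluation.

## Applicability domain

Reliability is scored per query as the maximum Tanimoto similarity to
any training fingerprint (exact linear scan; ties to the lowest training
index). Reports bin queries into similarity intervals of width 0.1
(left-closed, last bin closed) and split them at 0.6 — queries below 0.6
are outside the domain. Two-empty-fingerprint similarity is 0 by default
(an empty fingerprint is evidence of nothing); a flag restores the
Jaccard convention of 1. Statistics of a bin that lacks a class are
reported as `NA`, never silently 0, and inside+outside confusion counts
pool exactly to the global matrix — an identity the tests assert.

## The synthetic world

`synth_spec()` describes a dataset with known ground truth; generators
are pure functions of (spec, seed). Defaults mirror the curated
collection this recipe was designed for: ~1:28 imbalance (50 positives /
1,400 negatives at package-test scale), informative descriptors with a
standardized class separation of 1.5, noise descriptors, correlated
copies (parent + jitter, |r| > 0.9), constant columns, class-dependent
fingerprint bits (on-rates 0.6 vs 0.1 over a 0.05 background), and
contradictory assay reports at rate 0.05. The `"ga"` preset (200 + 200,
30 descriptors, 5 informative) mirrors the balanced trimmed set used
during subset search. Planted conflicts are exact 2-of-3 splits so the
strict agreement rule must exclude them — which makes "excluded count =
planted conflicts" a checkable identity rather than a tendency; planted
IC50-versus-percent disagreements are 2 + 2 ties resolvable only by IC50
priority.

What a green test does **not** establish: the generator draws
independent Gaussian descriptors and independent Bernoulli bits, so it
contains no realistic chemistry — no scaffold structure, no
activity cliffs, no correlated fingerprint substructure, no
batch-by-database distribution shift. Recovery of planted descriptors
here demonstrates that the machinery optimizes what it claims to
optimize, not that any particular published descriptor list would be
re-derived.

## Numerical conventions

* Reported metrics round half-up to 3 decimals (matching how comparison
  tables are typeset); internal values keep full precision.
* Undefined ratios (zero denominators, chance agreement Pe = 1) are
  `NA`, never 0.
* The decision threshold is the SVM's native boundary (decision value
  ≥ 0); final-model threshold calibration is exposed as an argument but
  never applied silently.
* ROC AUC is the Mann–Whitney statistic with ties counted ½ —
  identical to trapezoidal ROC integration, with no interpolation
  choices.
* Similarity bin membership rounds `sim/width` to 9 decimals before
  flooring so that exact bin edges (0.6) land in their closed-left bin
  despite floating-point division.
* All randomness flows from one root seed through named substreams
  (`derive_seed(seed, "folds")`, `"ga"`, `"tabular"`, …), so any stage
  can be re-run independently and reproducibly.

## Known limitations

* The SMO solver precomputes the Gram matrix: O(n²) memory limits
  training to ≤ 8192 rows. Industrial-scale runs (hundreds of thousands
  of rows) would need a chunked kernel cache or an external solver.
* Non-dominated sorting is the O(n²) algorithm in R — fine for
  populations ≤ a few hundred, the regime this wrapper operates in.
* Descriptor computation itself (2D/3D physicochemical descriptors,
  fingerprint generation from structures) is out of scope: inputs are
  numeric tables and bit sets. No chemistry — no structure
  standardization, salt stripping, or tautomer handling — is performed,
  and `compound_key` is treated as an opaque standardized identifier.
* The curation agreement rule for exact ties beyond 3 reports follows
  the strict >2/3 reading throughout; other historical readings cannot
  be distinguished from published counts alone.
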