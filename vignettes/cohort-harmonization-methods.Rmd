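---
title: "Curation, harmonization and incremental learning across clinical cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation, harmonization and incremental learning across clinical cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where several
constructions were defensible.

## Setting and assumptions

The package targets multi-cohort clinical studies in which each centre
holds a patient-by-feature table with its own column names, value
encodings and units, and in which the prediction target is a rare binary
outcome (the motivating case is non-Hodgkin lymphoma in primary Sjögren's
Syndrome, with roughly 5% prevalence).  Three assumptions shape the
design:

* a **disease reference model** exists — a curated set of clinical terms
  with a class hierarchy and per-term value domains — and is the agreed
  harmonization target;
* patient-level data cannot be pooled; only model state may move between
  cohorts ("private spaces"), which motivates batch-wise *incremental*
  training rather than centralized fitting;
* tables are quality-impaired in mundane ways: missing cells, duplicated
  and near-empty columns, occasional unparseable or out-of-domain values,
  and (rarely) gross outlier cells.

## The reference model and the medical corpus

A reference model is a forest of terms, each with a value domain of kind
numeric (inclusive range plus unit label), categorical (ordered canonical
labels), binary (0 = absent, 1 = present) or date.  It serializes to a
single canonical JSON document (fixed key order, stored term order,
two-space indentation), so `save(load(f))` reproduces `f` byte for byte —
a deliberately boring format that diffs cleanly under version control.

Matching operates on the **medical corpus**, the flat projection of the
model: one entry per term with its synonyms, normalized tokens, value
domain and root-to-term class path.  Synonym enrichment sits behind a
pluggable *synonym source* (a named list or a function); the package
ships a compact built-in clinical lexicon, tests inject deterministic
stubs, and with no source the corpus is built fully offline.  Enrichment
only ever adds synonyms, so the enriched corpus is a superset of the
offline one for every term.

Grouping classes ("Demographics", "Laboratory", …) are terms of the
model, but only **leaf terms** describe measurable parameters, so
matching candidates and the coverage denominator are the leaves.  This
keeps the natural fixpoint property: a table whose columns are exactly
the canonical parameter names reaches 100% coverage.

## Curation

Curation runs in a fixed order — profile, drop bad features, drop
inconsistent features, drop duplicate columns, blank outlier cells,
impute — and never drops rows.  Every action (column drop, cell blank,
cell imputation) is recorded, and replaying the log on the raw table
reproduces the curated table cell for cell.  All thresholds are
configuration keys:

| parameter | default | meaning |
|---|---|---|
| `bad_missing_threshold` | 0.5 | features missing more than this fraction (or constant) are dropped |
| `inconsistency_tolerance` | 0.05 | tolerated fraction of values violating the observed kind or mapped domain |
| `duplicate_agreement` | 0.99 | value-agreement fraction on co-present rows that flags a duplicate pair |
| `outlier_fence` | 3 | IQR multiplier for the outlier fences |
| `outlier_min_values` | 8 | fewer non-empty values ⇒ the feature is skipped, not judged |
| `missing_tokens` | "", NA, N/A, NaN, null, "-" | case-insensitive empty-cell lexicon |

Observed kinds are inferred by majority vote over non-empty cells;
numeric-parseable majorities whose values are all 0/1 are binary.
Numeric imputation uses the median (robust to the same skew that triggers
outlier flags); categorical and binary imputation uses the mode with ties
broken by the lexicographically smallest label, so the result never
depends on row order.

One deviation from the textbook fence deserves its rationale.  Quartiles
for the `[Q1 − 3·IQR, Q3 + 3·IQR]` fences are computed on the **distinct**
non-empty values of a feature rather than on all values.  Median
imputation places a large point mass at one value; on re-profiling, plain
quartiles collapse the IQR onto that spike and the fences would flag a
fifth of perfectly ordinary cells, which both breaks the idempotence
contract (`curate(curate(T)) = curate(T)`) and misreads an imputation
artifact as outliers.  Distinct-value quartiles are insensitive to mass
duplication, leave genuinely spread data untouched, and keep the
convention that a constant feature has collapsed fences and no outliers.

## Harmonization

All name comparisons share one normalization: lowercase; `_`, `-`, `/`
become spaces; other punctuation is stripped; whitespace collapses; the
result splits into tokens.  Lexical similarity is normalized Levenshtein
on the space-joined forms, `1 − d(a, b)/max(|a|, |b|)`, implemented via
`utils::adist` and cross-checked in the tests against an independent
dynamic-programming oracle.

Matching is two-stage, mirroring how a human aligns a codebook: first
**lexical** (candidate score = best similarity against any synonym of a
term; greedy acceptance by descending score, ties broken
lexicographically by term then column, subject to injectivity and a 0.80
threshold), then **semantic** on the residue only (token-level
synonym-aware similarity averaged over the column's tokens, weight 0.8,
plus a 0.2-weighted class-path bonus — the best token-overlap fraction
with any ancestor class; threshold 0.60).  Greedy assignment rather than
optimal bipartite matching is deliberate: it is deterministic, auditable,
and at cohort scale (tens of columns) the two rarely differ.

Value standardization recodes categorical labels to reference categories
by label similarity (below 0.5 the configured `unknown` label is used,
with a warning), maps binary vocabularies ({yes, y, true, 1, present} /
{no, n, false, 0, absent}) onto 0/1, and rescales numerics only when an
explicit conversion is configured for the term — units are never guessed.

The harmonized output uses canonical leaf-term names as columns in
depth-first model order.  By default **all** leaf terms appear, with `NA`
columns for unmatched terms, so any set of cohorts harmonized against one
model shares a schema — the property both the consistency check and the
federated protocol rely on; `schema = "matched"` restricts the output to
accepted terms.

## The consistency check

Principal components are fitted once on the z-scored integrated dataset
(zero-variance columns dropped with a warning), using an
eigendecomposition of the correlation matrix; components are ordered by
eigenvalue and signed so each component's largest-magnitude loading is
positive.  Each cohort's rows are projected into this shared basis and
the cohort's PC1/PC2 score distributions are compared with two-sided
Wilcoxon rank-sum tests at `alpha = 0.05`.

The comparison sample is, by default, the **remaining pooled rows** rather
than the full integrated dataset.  The two choices test the same
scientific question in the same basis, but a cohort is a subset of the
integrated data, and the rank-sum test of a sample against a pool
containing it is severely conservative (simulated type-I error below 0.01
at nominal 0.05).  Testing against the complement keeps the two samples
independent, so the test holds its nominal size — the calibration the
package's own acceptance suite verifies (empirical rejection 0.05 ± 0.02
under the null over 500 simulations).  `reference = "pooled"` restores the
literal cohort-versus-integrated comparison.  A single-cohort input has an
empty complement and passes trivially with p = 1.

P-values are exact by enumeration of rank assignments when the combined
sample size is at most 12 with no ties, and otherwise use the normal
approximation with tie-corrected variance and continuity correction; the
statistic is the rank sum of the first sample under midranks, making the
test invariant to strictly monotone transforms.

## Incremental learning across private spaces

A training plan fixes an ordered list of training spaces, one test space,
an algorithm, the number of runs (default 5, seeds 0–4) and the control
ratio (default 2).  Per run:

1. in every training space, **matched downsampling** selects, per case
   (case order randomized by the run seed), `ratio` same-sex controls of
   minimal absolute age difference, without replacement (ties to the
   smaller row index; nearest-age any-sex fallback with a warning when
   same-sex controls run out; all controls with a warning when too few
   exist).  No age caliper is applied; the achieved mean age gap is
   recorded for audit;
2. feature **encoding** and **min-max scaling to [0, 1]** are fitted on
   the first space's batch and frozen — nothing about the test space ever
   reaches a fitted transform.  The scaling is required by multinomial
   NB's nonnegativity and applied to every family for comparability.
   Categorical terms are one-hot encoded, and numeric terms are
   additionally expanded into quartile-bin indicators (breakpoints from
   the first batch): a count-based model cannot exploit a continuous lab
   value as a fractional count, and binning is the standard remedy —
   redundant but harmless for the tree, margin and network families;
3. **hyperparameters** are selected on the first batch by exhaustive grid
   search with stratified 3-fold cross-validation, repeated over three
   fold assignments and averaged (the batches are small, and a single
   fold split selects noisily); ties go to the earliest grid row.
   Defaults: boosted trees rounds {15, 30} × depth {2, 3} × learning rate
   {0.05, 0.1} with 0.8 row/column subsampling; SVM/logistic L2 strength
   {1e-4, 1e-3, 1e-2}; MLP hidden size {16, 32} at 20 epochs per batch;
   NB smoothing {1, 2, 5}.  These are deliberately conservative: matched
   batches hold tens of rows, and aggressive settings overfit them;
4. the model is **fitted on the first batch and updated** through the
   remaining spaces in order; a single-class batch is skipped with a
   warning.  Incremental contracts per family: NB accumulates class and
   feature sufficient statistics (sequential updates over any partition
   equal the pooled fit exactly); linear SVM and logistic regression take
   stochastic-gradient passes (hinge/log loss, 100 epochs per batch, step
   size decaying with the cumulative step count so later batches continue
   the schedule); the MLP warm-starts from its current weights; XGBoost
   appends rounds trained with the existing ensemble's margin as base
   margin, and prediction chains the margins in order;
5. **evaluation** uses the full test cohort — never downsampled, since a
   deployed model faces the natural case mix — with the class decision at
   probability 0.5, a threshold-swept ROC, and trapezoidal AUC (equal to
   the concordant-pair statistic with ties at one half).  The summary is
   each metric's mean ± SD over runs.

Rule extraction fits a single shallow surrogate regression tree (depth ≤ 3,
complexity 0.05, minimum leaf 10) to the boosted model's predicted
probabilities on the pooled training batches; leaves report the mean
predicted class-1 probability, and the ensemble's gain-ranked features are
reported alongside.  The tight pruning is intentional: the surrogate is a
communication device and weak tail splits would only reproduce the
ensemble's noise.

## What the synthetic generator emulates — and what it does not

`generate_study()` draws four cohorts (default sizes 400, 400, 200, 200;
train three, test one) from one latent model: shared per-term
distributions, a shared logistic outcome model whose intercept is
calibrated by root-finding to 5% prevalence per cohort, per-cohort header
perturbation (character edits up to `edit_fraction = 0.10` of a name,
synonym swaps from the built-in lexicon with probability 0.3,
case/separator noise), encoding variants (yes/no, TRUE/FALSE,
capitalized categories), MCAR missingness at per-cohort rates (0.30,
0.22, 0.15, 0.10) injected as exact per-column counts into non-essential
columns, and one duplicated, one all-missing and one corrupted-numeric
defect column per cohort.  The outcome, age and sex columns stay complete
— they drive matching and evaluation, and registry outcome and
demographic fields are, in practice, the well-kept ones.  If a Bernoulli
draw yields fewer than `min_cases = 3` cases, the highest-risk rows are
set to cases so that matching and evaluation stay defined.

Several generator defaults are calibrated choices rather than neutral
ones, and the reasoning belongs here:

* **Cohort sizes.** With 5% prevalence, a 100-row test cohort holds about
  five cases, and the AUC of even the true risk score then swings by ±0.1
  across draws; no training procedure can be meaningfully scored against
  that noise.  Sizes (400, 400, 200, 200) keep desk-scale runtimes
  (seconds) while the held-out cohort carries ~10 cases.
* **Missingness rates.** Real cohort reports quote total missingness of
  roughly 17–45%, but those totals are dominated by near-empty columns
  that curation discards as bad features.  The generator models such
  columns as explicit defect columns and injects (0.30, 0.22, 0.15, 0.10)
  into the retained columns — the missingness that actually survives to
  imputation — preserving the ordering across cohorts.
* **The planted signal.** Effects are spread over nine terms (low C4 and
  C3, lymphadenopathy, salivary gland swelling, Anti-La, rheumatoid
  factor, dry eyes, female sex, age) with large log-odds.  Two failure
  modes drove this: a single dominant effect washes the others out of the
  case population under rare-outcome logistic selection, and a case
  missing its one dominant predictor becomes unrankable.  Redundant
  moderate-to-strong effects fix both.  The magnitudes are deliberately
  stronger than published clinical odds ratios: the generator is a
  *recovery* benchmark — it establishes that the pipeline finds structure
  that is genuinely there (a pooled logistic oracle on clean data clears
  AUC 0.85, the package's calibration floor) — not an epidemiological
  simulation.

What it does **not** emulate: real marginal distributions or inter-feature
correlation of clinical variables (features are conditionally independent
given the outcome), informative missingness (MCAR only), measurement
drift between centres, longitudinal structure, or free-text fields.
Passing the pipeline on these fixtures therefore demonstrates mapping
recovery, protocol correctness and signal recovery under schema noise —
not performance on any real registry.

## Numerical choices and degenerate inputs

Exact-versus-approximate switching for the rank-sum test happens at a
combined sample size of 12; quantiles are linear-interpolation (type 7)
throughout; PCA signs follow the largest-loading convention so results
are solver-independent; greedy matching breaks score ties
lexicographically; imputation breaks mode ties lexicographically; a
zero-range feature min-max-scales to 0; unseen categories one-hot encode
to all zeros; missing feature values reaching a fitted model are set to
the scaled midpoint 0.5.  Empty samples, single-class batches at first
fit, single-class test sets, all-features-dropped tables and cyclic or
dangling parent links are errors with named messages; a single-class
*update* batch and an unavailable synonym source degrade with warnings
instead, because both occur routinely in legitimate runs.

## Known limitations

Semantic matching is token-based; it will not bridge vocabulary gaps that
share no tokens or lexicon synonyms (no embedding or UMLS backend).  Unit
conversion requires explicit configuration.  The duplicate detector
compares columns pairwise, which is quadratic in the column count —
irrelevant at clinical-registry widths, noticeable beyond thousands of
columns.  The incremental SVM/logistic surrogates are SGD approximations
whose final state depends on batch order, as in any online scheme.  The
federation here is an in-process scheduler over local partitions: no
transport, authentication or secure aggregation is provided, and nothing
beyond model state is exchanged by construction rather than by
cryptographic guarantee.
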