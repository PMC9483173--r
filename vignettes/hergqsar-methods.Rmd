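---
title: "Methods: ligand-based hERG blockade classification with hergqsar"
author: "hergqsar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based hERG blockade classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `hergqsar`, the
assumptions and tunable parameters of each stage, the design decisions made
where the procedure was genuinely open, and the limits of what the test
suite demonstrates. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem and the model

Blockade of the hERG potassium channel is assessed experimentally as an
IC50; on the pIC50 = −log₁₀(IC50/M) scale, the field separates blockers
(ACT) from non-blockers (INA) at pIC50 = 6 (IC50 ≤ 1 µM, the stricter
safety-relevant cutoff) or pIC50 = 5 (IC50 ≤ 10 µM). `hergqsar` builds
binary classifiers at either threshold from curated structure–activity
tables. The modeling assumptions are those of any ligand-based QSAR:
activity is a function of 2D structure expressible through molecular
descriptors, the training chemistry bounds the region where predictions are
meaningful (hence an explicit applicability domain), and replicate
measurements of one compound scatter around a common true value (hence
replicate aggregation with an outlier rule).

A note on the class-boundary direction: IC50 ≤ 1 µM corresponds to
pIC50 ≥ 6 under the −log transform, so `assignLabel()` uses
**ACT ⇔ pIC50 ≥ threshold**; the boundary value itself is ACT.

## Curation

`curateActivityData()` applies, in order:

1. **Entry filters** — keep records with `standard_type == "IC50"` (or
   comment-only "not active" records), `target_organism == "Homo sapiens"`,
   `assay_type == "B"` (direct binding), and an empty
   `data_validity_comment`. Each rejection is logged with the first failing
   rule. Rationale for keeping comment-only inactives: qualitative
   non-activity is information about the negative class; such compounds are
   labeled INA at both thresholds and never enter numeric aggregation. When
   a compound has both numeric records and a "not active" comment, the
   numeric records win.
2. **Structure standardization** — stereochemistry descriptors are removed
   (2D descriptors cannot see them), counterions are stripped by keeping
   the largest organic fragment, charges are neutralized where chemically
   valid, and the result is canonicalized (OpenBabel). Rejections:
   inorganics (no carbon), compounds with elements outside
   {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I} (covers organometallics and
   exotic elements), true multi-component mixtures (two organic fragments
   each with more than 6 heavy atoms — smaller second fragments are treated
   as counterions), and unparseable strings. The parser is as lenient as
   OpenBabel itself; a character-level syntax gate catches non-SMILES text
   before any toolkit call.
3. **pIC50 conversion** — units M/mM/µM/nM are converted to molar first;
   non-positive values or unknown units are rejected with a reason.
4. **Replicate aggregation** — per canonical structure, the mean pIC50 is
   kept and the replicate spread σ is the *sample* standard deviation
   (n − 1 denominator; 0 for singletons). Compounds with σ > 2 are
   excluded outright: a 100-fold disagreement between replicates means the
   underlying measurements cannot be trusted. The sample (not population)
   definition is the standard choice for replicate measurements; the
   source protocol does not specify one.

## Descriptors

The built-in backend (`obgraph2d`) is deliberately open and
license-free: OpenBabel physicochemical properties (MW, logP, TPSA, molar
refractivity, H-bond donors/acceptors) plus element counts and
graph-topological indices (Wiener, Harary, Zagreb 1/2, Randić, Balaban J,
eccentricity-based) on the heavy-atom graph — about 30 conformer-free 2D
descriptors. Commercial descriptor sets used in the literature are much
larger (~thousands of descriptors before pruning); the pipeline is
descriptor-agnostic and accepts any precomputed compounds × descriptors
CSV, so such sets can be dropped in where licensed. Descriptor counts
reported downstream (e.g. how many survive selection) are therefore
backend-dependent outcomes, not parameters.

Pruning removes, in order: descriptors with any missing value; descriptors
with sd < 0.01 (near-constant); and for every pair with |Pearson r| > 0.95,
the later descriptor in name-sorted order. The survivor rule is arbitrary
by necessity — the 95% rule does not say which of a pair to keep — and the
fixed name order makes it deterministic, which matters more than the
particular choice. Normalization is z-scoring; validation/external sets
always reuse the training means and standard deviations verbatim.

## Rational splitting

Within each class independently, greedy MaxMin picking on Tanimoto
distance between Morgan fingerprints selects the most diverse
round(0.8·n_class) compounds for training; the rest form the validation
set. Per-class operation preserves the INA:ACT ratio to within one
compound. Design decisions:

* **Fingerprints** — ECFP-style circular fingerprints, radius 2, 2048
  bits, computed natively on the connection table with invariants
  (element, heavy degree, total bond order, ring membership) and iterative
  neighborhood hashing. Radius and width are the conventional defaults.
  Bit positions are specific to this implementation's hash; all uses are
  internal (similarities), so cross-toolkit bit compatibility is not
  needed and not claimed.
* **Initialization** — the first pick is the compound with the largest
  fingerprint popcount, ties broken lexicographically by id. A fixed rule
  makes splits reproducible and order-invariant; a seed-randomized start
  (`randomStart = TRUE`) is available.
* **Tie-breaks** — among equal MaxMin distances, lexicographic id order.
* **Empty fingerprints** — Tanimoto of two all-zero vectors is defined as
  1 (identical emptiness), distance 0.
* When the input has no structures (precomputed descriptor matrices), the
  pipeline falls back to a seeded stratified random split with the same
  per-class arithmetic, since fingerprints are undefined there.

`pcaCoverage()` reports the variance captured by the first two principal
components of the pooled property block and each subset's score bounding
box, the usual visual check that training and validation occupy the same
region of property space.

## Feature selection (three-step random-forest procedure)

Run on the training set only, to keep validation data out of every
modeling decision:

1. **Ranking** — mean and sd of unscaled permutation importance over
   `nRuns` independently seeded forests (defaults: 25 runs, 500 trees,
   mtry = √p).
2. **Threshold step** — a CART regression of sd(importance) against rank
   (standard `rpart` controls, minsplit 20, cp 0.01); the minimum fitted
   value is the threshold, and features with mean importance below it are
   discarded. Under pure noise the mean importances scatter around zero
   while the threshold tracks their spread, so the retained set is small.
3. **Interpretation step** — nested forests on the top-k features,
   k = 1…|retained|; the smallest k whose mean out-of-bag (OOB) error is
   within one standard deviation of the minimum is kept (1-SD rule).
4. **Prediction step** — a greedy forward pass over the interpretation set
   in rank order; a feature enters only if it lowers the OOB error by more
   than a jump threshold equal to the mean absolute difference between
   successive nested models in the presumed-noise tail of the ranking
   (models extending the interpretation set with retained-but-not-kept
   features). Estimating the jump from that tail — i.e. from the
   fluctuation scale of an *adequate* model — rather than from noise-only
   models is deliberate: noise-only models sit at the majority-class error
   plateau, where OOB fluctuations are an order of magnitude larger, which
   would make the pass refuse genuinely informative additions. Error
   estimates in this step are averaged over `nFor` forests (default 5) for
   stability.

Nesting (prediction ⊆ interpretation ⊆ threshold ⊆ all) is a class
invariant. All randomness derives from one recorded master seed. Whether
to iterate the whole procedure over several seeds is left to the user; a
single seeded run is the default.

## Imbalance handling

At the stricter threshold, curated hERG data are strongly unbalanced
(about 5 non-blockers per blocker). Two standard remedies are provided:

* **SMOTE** (`smote()`): the minority class is oversampled to *exactly*
  1:1 by interpolating each minority sample toward one of its k = 5
  nearest minority neighbors (Euclidean distance in the normalized
  selected-feature space) with a Uniform(0,1) weight; k = 5 is the
  canonical default. Each minority row receives ⌊need/n_min⌋ synthetic
  points and the remainder is drawn uniformly at random (seeded). SMOTE is
  applied to the training partition only — the validation set stays
  unbalanced so that reported performance reflects the real class
  distribution — and runs after feature selection, in the selected
  descriptor space (selection is training-only either way, so the order
  does not leak information). Synthetic points exist only in descriptor
  space; no structures are fabricated, and the applicability domain is
  fitted on the original (pre-SMOTE) rows because it describes real
  chemical space.
* **Balanced random forest** (`BRF`): every tree trains on an equal-size
  per-class bootstrap (n_min draws with replacement from each class,
  `balancedBootstrap()`). BRF and SMOTE are not combined by default (the
  two balancing mechanisms are redundant); `allowBrfSmote = TRUE`
  overrides.

## Models, tuning and consensus

Seven algorithm ids cover six classifier families: BRF/RF (random
forests), KNN, GB and XGB (gradient boosting — both on the xgboost
backend, GB restricted to plain depth-wise boosting without stochastic
subsampling, XGB with regularization and subsampling in its search
space), MLP (single-hidden-layer perceptron, `nnet`), and RBF-kernel SVM
with Platt probability estimates. Hyperparameters are chosen by mean
balanced accuracy under stratified 5-fold cross-validation; folds
preserve the class ratio to within one compound. BRF, RF, KNN, GB and MLP
use exhaustive grids of literature-standard values; the larger SVM and
XGB spaces are explored by a seeded random search capped at `budget`
configurations (default 10) — a pragmatic stand-in for more elaborate
sequential optimizers that changes tuning cost, not the method. Ties in
the search are broken by fixed grid order. The winner is refit on the
full training data. Class calls use the 0.5 probability cutoff; no
threshold tuning is attempted.

The consensus (`consensusPredict()`) emits a class only when all members
(2–3 bundles sharing a threshold) concord; otherwise the compound is
ABSTAIN and excluded from scoring, with abstention counts reported. With
two members, majority and unanimity coincide; for three members a
strict-majority mode exists but unanimity is the default, since
concordance is the point of the exercise. The consensus score — needed
for an AUC — is the arithmetic mean of member probabilities; no published
definition exists for a concordance consensus, and the mean is the least
committal choice. Members are picked by validation BA, then AUC.

## Applicability domain

`fitAD()` stores (X′X)⁻¹ of the normalized, feature-selected,
pre-SMOTE training matrix (Moore–Penrose pseudoinverse when singular —
descriptors surviving the 0.95 correlation prune can still be exactly
collinear); the leverage of a query is h = x′(X′X)⁻¹x and compounds with
h > 3p/n are out of domain. A compound exactly at the cutoff is *in*
domain (the exclusion is strictly "greater than"). The hat-matrix trace
identity (Σh over training rows = rank(X), = p at full rank) is enforced
in the tests at 1e-6. The AD is fitted per model bundle on that bundle's
feature set. Validation metrics are computed over in-domain,
non-abstained rows only, with both exclusion counts reported.

## Synthetic data: what it emulates, and what it does not

`generateDescriptorDataset()` emulates the statistical skeleton of a
curated hERG dataset: an exact 5:1 (or 1:1) class ratio, a small set of
class-informative Gaussian descriptors (standardized mean shift =
`effectSize`, default 1.5) among many noise descriptors, for 600
compounds by default. `generateActivityTable()` emulates the raw export:
valid drug-like SMILES from an internal enumerated library (~700 distinct
scaffold × linker × tail structures), replicate IC50 records in mixed
units with controllable within-compound spread, a configurable fraction
of σ > 2 outlier compounds, comment-only inactives, and one record
violating each curation filter. Activity carries a latent
structure–activity signal (a standardized blend of lipophilicity and
size, 1.2 pIC50 units per SD by default) so descriptor models can
genuinely recover it; residual spread 0.8, location 5.5 — values typical
of curated potency data at this scale.

What passing tests on these fixtures shows: the machinery — filters,
aggregation, splitting arithmetic, selection nesting and recovery,
SMOTE geometry, leverage algebra, metric formulas, determinism — behaves
exactly as specified. What it does not show: performance on real hERG
chemistry. Gaussian descriptor clouds have no activity cliffs, no
correlated descriptor blocks tied to scaffolds, and no assay
heterogeneity; the SMILES library spans a far narrower chemistry than
ChEMBL. Dataset-level performances from the published benchmark
(BA up to ~0.9 on thousands of ChEMBL compounds with a commercial
descriptor set) are reproduced here only at the level their printed
confusion matrices allow: the metric arithmetic is verified cell by cell,
not re-derived from raw data.

The bundled reference tables (`inst/extdata/`) digitize that benchmark's
printed confusion matrices. Three rows are flagged as errata: their
printed metrics are inconsistent with their own printed counts (beyond
one unit in the last printed digit); the tests assert that the metric
suite *detects* these inconsistencies rather than pretending to match
them.

## Numerical choices and degenerate inputs

* MCC is computed in floating point (no integer overflow) and defined as
  0 when a marginal is zero; SE/SP raise an error when a true class is
  empty rather than returning NaN.
* AUC is the Mann–Whitney rank statistic with ties counted ½, which
  equals trapezoidal ROC integration; agreement with an O(n²) pairwise
  oracle is tested at 1e-12.
* Report rounding is half-up to 2 decimals (table convention); internal
  values are never rounded.
* Every randomized operation derives its own sub-seed from the master
  seed plus a stage tag, so stage results are independent of each other's
  random consumption and the whole pipeline is bitwise-reproducible.
* Problem sizes in the test suite are desk-scale by design: selection
  properties use 600 × 55–60 matrices with 5 ranking forests of 100
  trees; the end-to-end suite uses 600 compounds × 60 descriptors. These
  sizes are stated here as the package's validation conditions.

## Known limitations

* The open descriptor backend is small (~30 descriptors); models built on
  it are weaker than those from large commercial descriptor sets, and
  descriptor-count outcomes are not comparable across backends.
* Morgan bit positions are implementation-specific (internal use only).
* KNN probability granularity is 1/k, so its AUC is coarse.
* No probability calibration, stacking, deep-learning families, tautomer
  handling or InChI support; external/temporal sets are user-supplied
  inputs, never produced by the splitter.
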