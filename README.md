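# hergqsar

Ligand-based classification of hERG potassium-channel blockade.

Off-target blockade of the cardiac hERG channel causes drug-induced QT
prolongation and potentially fatal arrhythmia, so flagging likely blockers
early is a standard step in preclinical safety assessment. `hergqsar`
implements a complete, tested QSAR workflow for building and applying
binary hERG blocker/non-blocker classifiers from ChEMBL-style activity
exports, at the two potency thresholds used in the field:

* **ACT** (blocker) if pIC50 ≥ 6 (IC50 ≤ 1 µM), or pIC50 ≥ 5 (IC50 ≤ 10 µM),
  with pIC50 = −log₁₀(IC50 in molar);
* **INA** (non-blocker) otherwise.

## What the package does

1. **Curation** — entry filters (IC50 only, human target, direct-binding
   assays, no validity warnings), SMILES standardization (salt stripping,
   charge neutralization, stereochemistry removal, canonicalization via
   OpenBabel; organometallics/inorganics/mixtures rejected), pIC50
   conversion, replicate aggregation with a σ > 2 outlier rule, and
   dual-threshold labels.
2. **Descriptors** — an open 2D backend (OpenBabel physicochemistry plus
   graph-topological indices), or any precomputed descriptor CSV; pruning
   (missing values, sd < 0.01, |r| > 0.95) and z-normalization with
   training statistics reused verbatim on external sets.
3. **Rational splitting** — per-class MaxMin diversity picking on Morgan
   fingerprints under Tanimoto distance (80/20 by default, class ratios
   preserved), plus a PCA coverage check.
4. **Feature selection** — three-step random-forest selection on the
   training set only: permutation-importance ranking, a CART-based
   importance threshold, a nested-model interpretation step (1-SD rule)
   and a redundancy-pruning prediction step.
5. **Imbalance handling** — SMOTE oversampling to an exact 1:1 ratio
   (training set only), and balanced random forests via equal-size
   per-class bootstraps.
6. **Modeling** — six classifier families (BRF, RF, KNN, GB, XGB, MLP,
   SVM) tuned by stratified 5-fold cross-validated balanced accuracy
   (grid search; budgeted random search for the larger SVM/XGB spaces).
7. **Applicability domain** — leverage h = x′(X′X)⁻¹x with the 3p/n
   cutoff; validation metrics are reported for in-domain compounds.
8. **Consensus** — an abstaining consensus that emits a class only when
   all member models concord; metrics: SE = TP/(TP+FN), SP = TN/(TN+FP),
   BA = (SE+SP)/2, MCC, and rank-based ROC AUC.

A synthetic-data module generates both labeled descriptor datasets
(planted informative features among noise, exact class ratios) and raw
ChEMBL-style activity tables (replicates in mixed units, σ-outliers,
filter-violating records) so every stage is testable without any external
database.

## Worked example

```r
library(hergqsar)

# a synthetic ChEMBL-style export: 150 compounds, replicate IC50 records
# in mixed units, sigma-outliers and filter-violating rows included
tab <- generateActivityTable(nCompounds = 150, seed = 7)

res <- runTrainingPipeline(list(
  activity   = tab$records, threshold = 5,
  algorithms = c("BRF", "KNN", "SVM"), smote = TRUE,
  seed = 7, select = FALSE, outDir = "hergq_run5"))
res$metrics[, c("model", "BA", "SE", "SP", "MCC", "AUC", "n_abstained")]
#>                 model   BA   SE   SP  MCC  AUC n_abstained
#> 1                 BRF 0.75 0.82 0.67 0.50 0.90           0
#> 2                SKNN 0.69 0.88 0.50 0.42 0.75           0
#> 3                SSVM 0.76 0.94 0.58 0.58 0.92           0
#> 4 CONSENSUS(SSVM+BRF) 0.78 0.93 0.64 0.61 0.92           3
```

The validation-set table mirrors the usual reporting layout: Cooper
statistics, MCC and AUC per model, with the consensus of the two
top-performing members last. The consensus abstained on 3 of 29
validation compounds (discordant member votes) and outperformed each
member on the rows it did predict.

Prediction on new structures returns per-model calls, the consensus call,
its mean probability score, and the applicability-domain flag:

```r
predictHerg(c("CCc1ccc(CC(=O)N(C)C)cc1",
              "C(F)(F)(C(F)(F)F)C(F)(F)C(F)(F)C(F)(F)F"), "hergq_run5")
#>                        canonical_smiles call_BRF call_SKNN call_SSVM consensus
#> 1               CCc1ccc(cc1)CC(=O)N(C)C      ACT       ACT       ACT       ACT
#> 2 FC(C(C(F)(F)F)(F)F)(C(C(F)(F)F)(F)F)F      ACT       ACT       ACT       ACT
#>   consensus_score applicability_domain
#> 1       0.8488506                 TRUE
#> 2       0.8048459                FALSE
```

The drug-like query is inside the training chemical space
(`applicability_domain = TRUE`), so its consensus call is trustworthy;
the perfluorinated chain is structurally alien to the training set and is
flagged out of domain — its prediction is reported but should not be
relied on.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/hergqsar.R` (verbs: curate, descriptors, split, select, train,
evaluate, predict, synth).

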