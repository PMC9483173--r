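Reference fixtures from a published hERG blockade classification benchmark
(ligand-based QSAR classifiers at potency thresholds pIC50 = 6 and 5).

reference_confusion_counts.csv
  Printed validation/external-set confusion matrices (TP/FP/TN/FN) and the
  metrics printed alongside them (BA/SE/SP/MCC/AUC, 2 decimals). Used to
  verify the metric suite: SE/SP/BA/MCC recompute from the counts. The
  `erratum` column flags rows whose printed metrics are internally
  inconsistent with their own printed counts (publication typos); tests
  assert that the recomputation detects these.

benchmark_composition.csv
  Dataset compositions (training/validation/external; before and after the
  leverage applicability-domain filter) of the same benchmark. Used as
  realistic problem sizes (n, p, class ratios) for imbalance handling and
  applicability-domain checks.
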