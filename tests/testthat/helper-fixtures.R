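# Shared fixtures, all built in code.

# round-half-up to 2 decimals, the printed-table convention
r2 <- function(x) floor(x * 100 + 0.5) / 100

# desk-scale selection parameters used throughout the suite
quickSel <- list(nRuns = 5, ntreeRank = 100, nForInterp = 5, ntree = 100)

# single-configuration search spaces so model tests don't pay for tuning
quickSpaces <- list(
  BRF = data.frame(ntree = 100, mtryMult = 1),
  RF = data.frame(ntree = 100, mtryMult = 1),
  KNN = data.frame(k = 5),
  GB = data.frame(nrounds = 50, eta = 0.3, max_depth = 3),
  XGB = data.frame(nrounds = 50, eta = 0.3, max_depth = 3,
                   subsample = 1, colsample = 1, lambda = 1),
  MLP = data.frame(size = 4, decay = 1e-2),
  SVM = data.frame(cost = 1, gamma = 0.1))

# two well-separated Gaussian clouds: any sensible classifier is near-perfect
separableData <- function(n = 120, p = 4, gap = 6, seed = 1) {
  stopifnot(n %% 2 == 0)
  y <- factor(rep(c("INA", "ACT"), each = n / 2), levels = c("INA", "ACT"))
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "ACT", 1] <- X[y == "ACT", 1] + gap
  colnames(X) <- paste0("d", seq_len(p))
  rownames(X) <- paste0("r", seq_len(n))
  list(X = X, y = y)
}

# handful of standardized structures for chemistry-level tests
testSmiles <- c("CCO", "c1ccccc1", "C1CCCCC1", "CCN(CC)CC",
                "Cc1ccccc1", "OCCN", "CC(=O)Oc1ccccc1C(=O)O",
                "Clc1ccccc1", "CCCCCCCC", "CC(C)CO")

refCountsPath <- function()
  system.file("extdata", "reference_confusion_counts.csv",
              package = "hergqsar")

refCompositionPath <- function()
  system.file("extdata", "benchmark_composition.csv", package = "hergqsar")
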