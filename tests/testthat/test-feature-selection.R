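test_that("importance ranking puts a planted feature on top", {
  d <- generateDescriptorDataset(n = 200, classRatio = c(1, 1),
                                 nInformative = 1, nNoise = 10,
                                 effectSize = 2.5, seed = 31)
  rk <- importanceRanking(d$X, d$y, nRuns = 5, ntree = 100, seed = 1)
  expect_equal(rk$name[1], "inf_01")
  expect_true(all(diff(rk$mean_importance) <= 0))
  expect_error(importanceRanking(d$X, rep("ACT", 200), nRuns = 2,
                                 ntree = 50, seed = 1), "single-class")
})

test_that("duplicate feature columns get near-equal importance", {
  d <- generateDescriptorDataset(n = 150, classRatio = c(1, 1),
                                 nInformative = 1, nNoise = 4,
                                 effectSize = 2, seed = 32)
  X <- cbind(d$X, dup_01 = d$X[, "inf_01"])
  rk <- importanceRanking(X, d$y, nRuns = 8, ntree = 100, seed = 2)
  a <- rk[rk$name == "inf_01", ]
  b <- rk[rk$name == "dup_01", ]
  tol <- 2 * max(a$sd_importance, b$sd_importance)
  expect_lt(abs(a$mean_importance - b$mean_importance), tol)
})

test_that("permuted labels collapse importances toward zero", {
  d <- generateDescriptorDataset(n = 150, classRatio = c(1, 1),
                                 nInformative = 3, nNoise = 7,
                                 effectSize = 2, seed = 33)
  rkTrue <- importanceRanking(d$X, d$y, nRuns = 8, ntree = 100, seed = 3)
  set.seed(5)
  yPerm <- sample(d$y)
  rkNull <- importanceRanking(d$X, yPerm, nRuns = 8, ntree = 100, seed = 3)
  # the largest null importance sits far below every planted importance
  planted <- rkTrue$mean_importance[rkTrue$name %in% d$planted]
  expect_lt(max(abs(rkNull$mean_importance)), min(planted) / 2)
  expect_lt(max(abs(rkNull$mean_importance)), 0.05)
})

test_that("threshold step keeps planted features and trims noise", {
  hits <- 0; kept <- numeric(10)
  for (s in 1:10) {
    d <- generateDescriptorDataset(n = 300, classRatio = c(1, 1),
                                   nInformative = 5, nNoise = 50,
                                   effectSize = 1.5, seed = 300 + s)
    rk <- importanceRanking(d$X, d$y, nRuns = 5, ntree = 100, seed = s)
    thr <- thresholdStep(rk)
    if (all(d$planted %in% thr)) hits <- hits + 1
    kept[s] <- length(thr)
  }
  expect_gte(hits, 9)
  # single feature input: identity
  rk1 <- data.frame(name = "only", mean_importance = 0.1,
                    sd_importance = 0.01)
  expect_equal(thresholdStep(rk1), "only")
})

test_that("all-noise input retains only a small feature set", {
  kept <- vapply(1:8, function(s) {
    d <- generateDescriptorDataset(n = 400, classRatio = c(1, 1),
                                   nInformative = 0, nNoise = 40,
                                   effectSize = 0, seed = 400 + s)
    rk <- importanceRanking(d$X, d$y, nRuns = 5, ntree = 100, seed = s)
    length(thresholdStep(rk))
  }, 1)
  # bounds frozen from a larger simulation of this oracle: under pure noise
  # the threshold step keeps ~10% of features on average, never the bulk
  expect_lte(mean(kept) / 40, 0.15)
  expect_lte(max(kept) / 40, 0.25)
})

test_that("interpretation step finds a separating singleton and nests", {
  sep <- separableData(n = 100, p = 1, gap = 8, seed = 41)
  X <- cbind(sep$X, noise1 = rnorm(100), noise2 = rnorm(100))
  keep <- interpretationStep(c("d1", "noise1", "noise2"), X, sep$y,
                             nFor = 5, ntree = 50, seed = 4)
  expect_equal(keep, "d1")
  expect_equal(interpretationStep("solo", X[, c(1, 2)], sep$y,
                                  nFor = 2, ntree = 20, seed = 1), "solo")
})

test_that("prediction step drops a redundant duplicate feature", {
  d <- generateDescriptorDataset(n = 200, classRatio = c(1, 1),
                                 nInformative = 2, nNoise = 6,
                                 effectSize = 2, seed = 42)
  X <- cbind(d$X, inf_dup = d$X[, "inf_01"] + rnorm(200, 0, 1e-6))
  interp <- c("inf_01", "inf_02", "inf_dup")
  retained <- c(interp, paste0("noise_0", 1:4))
  final <- predictionStep(interp, retained, X, d$y, ntree = 100, seed = 5)
  expect_true("inf_01" %in% final)
  expect_false("inf_dup" %in% final)
  expect_true(all(final %in% interp))
  # determinism
  final2 <- predictionStep(interp, retained, X, d$y, ntree = 100, seed = 5)
  expect_identical(final, final2)
})

test_that("the three stages are nested and recorded", {
  d <- generateDescriptorDataset(n = 240, classRatio = c(5, 1),
                                 nInformative = 3, nNoise = 12,
                                 effectSize = 1.8, seed = 43)
  sel <- do.call(selectFeatures,
                 c(list(X = d$X, y = d$y, seed = 6), quickSel))
  expect_true(all(selectedFeatures(sel) %in% sel@interpretationKept))
  expect_true(all(sel@interpretationKept %in% sel@thresholdKept))
  expect_true(all(sel@thresholdKept %in% colnames(d$X)))
  expect_equal(sel@params$seed, 6)
  # determinism of the full three-step run
  sel2 <- do.call(selectFeatures,
                  c(list(X = d$X, y = d$y, seed = 6), quickSel))
  expect_identical(selectedFeatures(sel2), selectedFeatures(sel))
  f <- tempfile(fileext = ".json")
  writeSelectionResult(sel, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$prediction_kept, selectedFeatures(sel))
})
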