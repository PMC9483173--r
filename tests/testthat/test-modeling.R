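test_that("every algorithm family separates an easy problem in CV", {
  sep <- separableData(n = 100, p = 4, gap = 6, seed = 71)
  for (alg in c("BRF", "RF", "KNN", "GB", "XGB", "MLP", "SVM")) {
    b <- tuneAndTrain(alg, sep$X, sep$y, searchSpace = quickSpaces[[alg]],
                      seed = 7, threshold = 6)
    expect_gte(b@cvMetrics$mean[["BA"]], 0.95)
    # deep-in-class training rows score confidently
    sc <- predictProba(b, sep$X)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(mean(sc[sep$y == "ACT"]), 0.9)
    # duplicated inputs give identical scores
    two <- predictProba(b, sep$X[c(1, 1), , drop = FALSE])
    expect_equal(two[1], two[2], tolerance = 1e-12)
  }
})

test_that("tuning is deterministic under a fixed seed", {
  d <- generateDescriptorDataset(n = 120, classRatio = c(1, 1),
                                 nInformative = 2, nNoise = 4, seed = 72)
  b1 <- tuneAndTrain("RF", d$X, d$y, seed = 9, threshold = 6)
  b2 <- tuneAndTrain("RF", d$X, d$y, seed = 9, threshold = 6)
  expect_identical(b1@hyperparameters, b2@hyperparameters)
  expect_equal(b1@cvMetrics$folds, b2@cvMetrics$folds, tolerance = 1e-12)
  sc1 <- predictProba(b1, d$X); sc2 <- predictProba(b2, d$X)
  expect_equal(sc1, sc2, tolerance = 1e-12)
  expect_error(tuneAndTrain("RF", d$X, d$y, searchSpace = data.frame(),
                            seed = 1), "empty")
})

test_that("random search respects its budget for the large spaces", {
  d <- separableData(n = 60, p = 3, gap = 5, seed = 73)
  b <- tuneAndTrain("SVM", d$X, d$y, budget = 3, seed = 3, threshold = 5)
  expect_true(is(b, "ModelBundle"))
  expect_equal(b@threshold, 5)
  full <- defaultSearchSpace("SVM", 3)
  expect_gt(nrow(full), 3)   # the space really is larger than the budget
})

test_that("stratified CV folds partition rows and preserve class ratio", {
  d <- generateDescriptorDataset(n = 150, classRatio = c(4, 1),
                                 nInformative = 2, nNoise = 3, seed = 74)
  cv <- kfoldCV("KNN", list(k = 3), d$X, d$y, k = 5, seed = 4)
  fold <- cv$fold_assignment
  expect_setequal(unique(fold), 1:5)
  expect_length(fold, 150)
  for (f in 1:5) {
    expect_equal(sum(fold == f), 30)
    expect_equal(sum(d$y[fold == f] == "ACT"), 6)  # 4:1 kept per fold
  }
  # reported mean equals the hand average of fold values
  expect_equal(unname(cv$mean[["BA"]]), mean(cv$folds$BA), tolerance = 1e-12)
  expect_error(kfoldCV("KNN", list(k = 3), d$X[1:4, ], d$y[1:4], k = 5,
                       seed = 1), "fewer rows than folds")
})

test_that("feature mismatches are reported by name", {
  sep <- separableData(n = 60, p = 3, gap = 5, seed = 75)
  b <- tuneAndTrain("RF", sep$X, sep$y, searchSpace = quickSpaces$RF,
                    seed = 2, threshold = 6)
  bad <- sep$X[, 1:2]
  expect_error(predictProba(b, bad), "d3")
})

test_that("consensus emits only concordant calls and conserves rows", {
  sep <- separableData(n = 80, p = 3, gap = 4, seed = 76)
  b1 <- tuneAndTrain("RF", sep$X, sep$y, searchSpace = quickSpaces$RF,
                     seed = 1, threshold = 6)
  b2 <- tuneAndTrain("KNN", sep$X, sep$y, searchSpace = quickSpaces$KNN,
                     seed = 1, threshold = 6)
  cons <- consensusModel(list(b1, b2))
  set.seed(77)
  Xq <- matrix(rnorm(40 * 3, mean = 3), 40, 3,
               dimnames = list(NULL, colnames(sep$X)))  # ambiguous region
  cp <- consensusPredict(cons, Xq)
  expect_equal(nrow(cp), 40)
  expect_true(all(cp$label %in% c("ACT", "INA", "ABSTAIN")))
  expect_equal(sum(cp$label != "ABSTAIN") + sum(cp$label == "ABSTAIN"), 40)
  # agreement logic: label iff both member votes coincide
  agree <- cp$vote_RF_1 == cp$vote_KNN_2
  expect_true(all((cp$label != "ABSTAIN") == agree))
  # score is the member mean
  p1 <- predictProba(b1, Xq); p2 <- predictProba(b2, Xq)
  expect_equal(cp$score, (p1 + p2) / 2, tolerance = 1e-12)
  # threshold mismatch is refused
  b3 <- tuneAndTrain("RF", sep$X, sep$y, searchSpace = quickSpaces$RF,
                     seed = 1, threshold = 5)
  expect_error(consensusModel(list(b1, b3)), "threshold")
})

test_that("consensus on concordant members outperforms chance abstention-free", {
  sep <- separableData(n = 100, p = 3, gap = 6, seed = 78)
  b1 <- tuneAndTrain("RF", sep$X, sep$y, searchSpace = quickSpaces$RF,
                     seed = 5, threshold = 6)
  b2 <- tuneAndTrain("SVM", sep$X, sep$y, searchSpace = quickSpaces$SVM,
                     seed = 5, threshold = 6)
  cp <- consensusPredict(consensusModel(list(b1, b2)), sep$X)
  keep <- cp$label != "ABSTAIN"
  consBA <- metricReport(sep$y[keep], cp$label[keep])$BA
  memberBAs <- c(
    metricReport(sep$y, ifelse(predictProba(b1, sep$X) >= 0.5,
                               "ACT", "INA"))$BA,
    metricReport(sep$y, ifelse(predictProba(b2, sep$X) >= 0.5,
                               "ACT", "INA"))$BA)
  expect_gte(consBA, min(memberBAs))
})

test_that("model bundles survive a save/load round trip", {
  sep <- separableData(n = 60, p = 3, gap = 5, seed = 79)
  for (alg in c("BRF", "XGB", "SVM")) {
    b <- tuneAndTrain(alg, sep$X, sep$y, searchSpace = quickSpaces[[alg]],
                      seed = 6, threshold = 6,
                      normStats = data.frame(name = colnames(sep$X),
                                             mean = 0, sd = 1),
                      adModel = fitAD(sep$X))
    dir <- tempfile()
    saveModelBundle(b, dir)
    expect_true(file.exists(file.path(dir, "meta.json")))
    back <- loadModelBundle(dir)
    expect_equal(predictProba(back, sep$X), predictProba(b, sep$X),
                 tolerance = 1e-10)
    meta <- jsonlite::read_json(file.path(dir, "meta.json"))
    expect_equal(meta$algorithm, alg)
  }
})
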