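test_that("Morgan fingerprints are deterministic and canonicalization-invariant", {
  fp <- morganFingerprint(c("CCO", "CCO", "CCCCCCCC"))
  expect_identical(fp[1, ], fp[2, ])
  expect_false(identical(fp[1, ], fp[3, ]))
  expect_equal(ncol(fp), 2048)
  # different SMILES writings of one molecule give identical bits
  a <- morganFingerprint(c("OCC", "c1ccccc1C"))
  b <- morganFingerprint(c("CCO", "Cc1ccccc1"))
  expect_identical(unname(a), unname(b))
  expect_error(morganFingerprint("][junk"), "unparseable")
})

test_that("tanimoto matches hand counts and conventions", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)   # identical emptiness
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("MaxMin picks the mutually farthest items first", {
  # A and C share nothing; B overlaps both; A has the largest popcount
  A <- c(rep(1, 9), rep(0, 11))
  C <- c(rep(0, 12), rep(1, 8))
  B <- c(rep(1, 4), rep(0, 8), rep(1, 4), rep(0, 4))
  fp <- rbind(A = A, B = B, C = C)
  labs <- rep("ACT", 3)
  # brute-force the greedy rule on this instance: start A, then the item
  # maximizing min distance to {A}: d(A,C)=1 > d(A,B) -> C
  sp <- maxMinSplit(fp, rownames(fp), labs, fraction = 2 / 3, seed = 1)
  expect_setequal(trainIds(sp), c("A", "C"))
})

test_that("MaxMin greedy agrees with a brute-force reimplementation", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 6
    fp <- matrix(rbinom(n * 24, 1, 0.4), n, 24)
    ids <- paste0("m", seq_len(n))
    rownames(fp) <- ids
    k <- 4
    # naive greedy oracle with the same start/tie rules
    tan <- function(a, b) { u <- sum(a | b); if (u == 0) 1 else sum(a & b) / u }
    D <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) 1 - tan(fp[i, ], fp[j, ])))
    pop <- rowSums(fp)
    start <- which(pop == max(pop))
    start <- start[order(ids[start])][1]
    picked <- start
    while (length(picked) < k) {
      md <- apply(D[, picked, drop = FALSE], 1, min)
      md[picked] <- -Inf
      cand <- which(md == max(md))
      picked <- c(picked, cand[order(ids[cand])][1])
    }
    sp <- maxMinSplit(fp, ids, rep("ACT", n), fraction = k / n, seed = 1)
    expect_setequal(trainIds(sp), ids[picked])
  }
})

test_that("split preserves class ratios and partitions the ids", {
  tab <- generateActivityTable(nCompounds = 60, seed = 5)
  cp <- compounds(curateActivityData(tab$records))
  ids <- cp$canonical_smiles
  fp <- morganFingerprint(ids)
  sp <- maxMinSplit(fp, ids, cp$label_t5, fraction = 0.8, seed = 2)
  expect_setequal(c(trainIds(sp), validIds(sp)), ids)
  expect_length(intersect(trainIds(sp), validIds(sp)), 0)
  for (lv in c("ACT", "INA")) {
    cls <- ids[cp$label_t5 == lv]
    expect_equal(sum(trainIds(sp) %in% cls),
                 floor(0.8 * length(cls) + 0.5))
  }
  # determinism
  sp2 <- maxMinSplit(fp, ids, cp$label_t5, fraction = 0.8, seed = 2)
  expect_identical(trainIds(sp2), trainIds(sp))
  # order invariance of the deterministic picker
  perm <- sample(length(ids))
  sp3 <- maxMinSplit(fp[perm, ], ids[perm], cp$label_t5[perm],
                     fraction = 0.8, seed = 2)
  expect_setequal(trainIds(sp3), trainIds(sp))
})

test_that("a 5:1 dataset splits 80/20 with 5:1 ratios in both halves", {
  d <- generateDescriptorDataset(n = 120, classRatio = c(5, 1),
                                 nInformative = 2, nNoise = 2, seed = 8)
  # fingerprint-free per-class split via the same arithmetic
  fp <- matrix(rbinom(120 * 32, 1, 0.3), 120, 32)
  rownames(fp) <- rownames(d$X)
  sp <- maxMinSplit(fp, rownames(d$X), d$y, fraction = 0.8, seed = 3)
  yTr <- d$y[match(trainIds(sp), rownames(d$X))]
  yVa <- d$y[match(validIds(sp), rownames(d$X))]
  expect_equal(as.vector(table(yTr)), c(80, 16))
  expect_equal(as.vector(table(yVa)), c(20, 4))
})

test_that("PCA coverage reports exact low-rank variance and nested boxes", {
  set.seed(9)
  basis <- matrix(rnorm(2 * 6), 2, 6)
  scores <- matrix(rnorm(80 * 2), 80, 2) %*% basis   # exact rank 2
  colnames(scores) <- paste0("p", 1:6)
  train <- scores[1:60, ]
  valid <- 0.5 * scores[61:80, ]   # shrunk toward centroid: inside the box
  rep <- pcaCoverage(train = train, valid = valid)
  expect_equal(rep$variance_explained_pc1_2, 1, tolerance = 1e-10)
  expect_true(rep$ranges$valid$pc1[1] >= rep$ranges$train$pc1[1] - 1e-8)
  expect_true(rep$ranges$valid$pc1[2] <= rep$ranges$train$pc1[2] + 1e-8)
  # identical sets give identical ranges
  rep2 <- pcaCoverage(a = train, b = train)
  expect_equal(rep2$ranges$a, rep2$ranges$b)
  expect_error(pcaCoverage(a = train[, 1, drop = FALSE]), "at least 2")
})
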