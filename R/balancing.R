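# Class-imbalance handling: SMOTE oversampling of the minority class in
# descriptor space (training set only) and the equal-size per-class bootstrap
# behind the balanced random forest.

#' SMOTE: synthetic minority oversampling
#'
#' Oversamples the minority class until the two classes are exactly 1:1.
#' Each synthetic row interpolates a minority sample x and one of its k
#' nearest minority neighbors x_nn (Euclidean distance in the normalized
#' feature space): x + u * (x_nn - x) with u ~ Uniform(0, 1). Every minority
#' row receives floor(need / n_min) synthetics; the remainder is drawn
#' uniformly at random. Synthetic points exist only in descriptor space —
#' no structures are fabricated — and must never be created from validation
#' or external rows.
#'
#' @param X numeric training matrix.
#' @param y ACT/INA labels.
#' @param k minority neighbors to interpolate with (default 5; clamped with
#'   a warning when the minority class is smaller than k + 1).
#' @param seed random seed.
#' @return an \linkS4class{AugmentedTrainingSet}; original rows first.
#' @export
smote <- function(X, y, k = 5, seed = 1) {
  y <- asClassFactor(y)
  stopifnot(nrow(X) == length(y))
  tab <- table(y)
  if (any(tab == 0)) stop("both classes must be present")
  minority <- names(tab)[which.min(tab)]
  nMin <- min(tab); nMaj <- max(tab)
  need <- as.integer(nMaj - nMin)
  empty <- data.frame(sample = integer(0), neighbor = integer(0),
                      weight = numeric(0))
  if (need == 0)
    return(new("AugmentedTrainingSet", X = X, y = y,
               syntheticMask = rep(FALSE, nrow(X)), parentPairs = empty))
  if (nMin < 2) stop("minority class needs at least 2 samples for SMOTE")
  if (k >= nMin) {
    warning("k clamped to minority size - 1 (", nMin - 1, ")")
    k <- nMin - 1
  }
  minIdx <- which(y == minority)
  Xm <- X[minIdx, , drop = FALSE]
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1, function(r) order(r)[seq_len(k)]),
               nrow = nMin, ncol = k, byrow = TRUE)
  perBase <- need %/% nMin
  rem <- need %% nMin
  synth <- matrix(NA_real_, need, ncol(X), dimnames = list(NULL, colnames(X)))
  pairs <- empty[rep(1, 0), ]
  withSeed(seed, {
    baseRows <- c(rep(seq_len(nMin), perBase),
                  if (rem) sample.int(nMin, rem) else integer(0))
    for (s in seq_along(baseRows)) {
      i <- baseRows[s]
      j <- nn[i, sample.int(k, 1)]
      u <- runif(1)
      synth[s, ] <- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
      pairs[s, ] <- list(minIdx[i], minIdx[j], u)
    }
  })
  rownames(synth) <- paste0("synthetic_", seq_len(need))
  new("AugmentedTrainingSet",
      X = rbind(X, synth),
      y = factor(c(as.character(y), rep(minority, need)),
                 levels = levels(y)),
      syntheticMask = c(rep(FALSE, nrow(X)), rep(TRUE, need)),
      parentPairs = pairs)
}

#' Equal-size per-class bootstrap samples
#'
#' For each tree of a balanced random forest, draws (with replacement)
#' n_min rows from every class, where n_min is the minority-class count, so
#' each tree trains on an exactly balanced sample.
#'
#' @param y ACT/INA labels of the training rows.
#' @param nTrees number of trees.
#' @param seed random seed.
#' @return list of integer index vectors, one per tree.
#' @export
balancedBootstrap <- function(y, nTrees, seed = 1) {
  y <- asClassFactor(y)
  tab <- table(y)
  if (any(tab == 0)) stop("both classes must be present")
  nMin <- min(tab)
  idxByClass <- split(seq_along(y), y)
  withSeed(seed, {
    lapply(seq_len(nTrees), function(t)
      unlist(lapply(idxByClass, function(ix)
        ix[sample.int(length(ix), nMin, replace = TRUE)]), use.names = FALSE))
  })
}
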