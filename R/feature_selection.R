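# Three-step random-forest variable selection (VSURF-style): permutation
# importance ranking with a data-driven threshold, a nested-model
# interpretation step, and a redundancy-pruning prediction step. Runs on
# training rows only; the API never sees validation data.

#' Permutation-importance ranking
#'
#' Fits \code{nRuns} independently seeded random forests and ranks features
#' by the mean (over runs) of unscaled permutation importance (mean decrease
#' in accuracy), together with its standard deviation.
#'
#' @param X numeric matrix (normalized training descriptors).
#' @param y ACT/INA labels.
#' @param nRuns forests to average over (default 25).
#' @param ntree trees per forest (default 500).
#' @param seed master seed.
#' @return data.frame(name, mean_importance, sd_importance), descending.
#' @export
importanceRanking <- function(X, y, nRuns = 25, ntree = 500, seed = 1) {
  y <- asClassFactor(y)
  if (length(unique(y)) < 2) stop("single-class labels")
  stopifnot(nrow(X) == length(y))
  mtry <- max(1L, floor(sqrt(ncol(X))))
  imps <- vapply(seq_len(nRuns), function(r) {
    withSeed(deriveSeed(seed, paste0("rank", r)), {
      rf <- randomForest::randomForest(X, y, ntree = ntree, mtry = mtry,
                                       importance = TRUE)
      randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    })
  }, numeric(ncol(X)))
  if (ncol(X) == 1) imps <- matrix(imps, nrow = 1)
  rk <- data.frame(name = colnames(X),
                   mean_importance = rowMeans(imps),
                   sd_importance = apply(imps, 1, sd))
  rk <- rk[order(-rk$mean_importance, rk$name), , drop = FALSE]
  rownames(rk) <- NULL
  rk
}

#' Threshold step: discard irrelevant features
#'
#' The importance standard deviation, as a function of rank, is fitted with
#' a piecewise-constant CART regression; the minimum fitted value is the
#' data-driven threshold, and features whose mean importance falls below it
#' are discarded. With pure-noise input the mean importances scatter around
#' zero while the threshold tracks their spread, so almost everything goes.
#'
#' @param ranking output of \code{\link{importanceRanking}}.
#' @return character vector of retained feature names, in rank order.
#' @export
thresholdStep <- function(ranking) {
  stopifnot(all(c("name", "mean_importance", "sd_importance") %in% names(ranking)))
  if (nrow(ranking) == 1) return(ranking$name)
  df <- data.frame(rank = seq_len(nrow(ranking)), s = ranking$sd_importance)
  fit <- rpart::rpart(s ~ rank, data = df, method = "anova",
                      control = rpart::rpart.control(minsplit = 20, cp = 0.01))
  thr <- min(predict(fit, df))
  ranking$name[ranking$mean_importance >= thr]
}

# OOB error on a feature subset, averaged over nFor seeded forests
oobError <- function(X, y, feats, ntree, seed, nFor = 1) {
  mean(vapply(seq_len(nFor), function(r) withSeed(
    deriveSeed(seed, paste0("f", r)), {
      rf <- randomForest::randomForest(X[, feats, drop = FALSE], y,
                                       ntree = ntree)
      unname(rf$err.rate[ntree, "OOB"])
    }), 1))
}

#' Interpretation step: smallest adequate nested model
#'
#' Fits forests on the top-k retained features for k = 1..|retained| and
#' returns the smallest k whose mean out-of-bag error is within one standard
#' deviation of the minimum mean OOB error across k (the classic 1-SD rule).
#'
#' @param retained rank-ordered names from \code{\link{thresholdStep}}.
#' @param X,y training data.
#' @param nFor forests per model size (default 10).
#' @param ntree trees per forest (default 100).
#' @param seed master seed.
#' @return character vector: the selected feature prefix.
#' @export
interpretationStep <- function(retained, X, y, nFor = 10, ntree = 100,
                               seed = 1) {
  if (!length(retained)) stop("empty retained set")
  y <- asClassFactor(y)
  if (length(retained) == 1) return(retained)
  errs <- sapply(seq_along(retained), function(k) {
    vapply(seq_len(nFor), function(r)
      oobError(X, y, retained[seq_len(k)], ntree,
               deriveSeed(seed, paste0("interp", k, "_", r))), 1)
  })
  meanErr <- colMeans(errs)
  sdErr <- apply(errs, 2, sd)
  kmin <- which.min(meanErr)
  kSel <- which(meanErr <= meanErr[kmin] + sdErr[kmin])[1]
  retained[seq_len(kSel)]
}

#' Prediction step: prune redundant features
#'
#' Greedy forward pass over the interpretation set in rank order: a feature
#' enters the final model only if it lowers the out-of-bag error by more
#' than a noise-scaled jump threshold. The threshold is the mean absolute
#' OOB difference between successive nested models in the presumed-noise
#' tail of the ranking — models that extend the interpretation set with the
#' retained-but-not-interpreted features — so it measures the fluctuation
#' scale of an adequate model, not the error of noise-only models.
#'
#' @param interpSet output of \code{\link{interpretationStep}}.
#' @param retained output of \code{\link{thresholdStep}} (superset).
#' @param X,y training data.
#' @param ntree trees per forest (default 100).
#' @param nFor forests averaged per error estimate (default 5).
#' @param seed master seed.
#' @return character vector: the final feature subset (nested in interpSet).
#' @export
predictionStep <- function(interpSet, retained, X, y, ntree = 100, nFor = 5,
                           seed = 1) {
  stopifnot(all(interpSet %in% retained))
  y <- asClassFactor(y)
  nInterp <- length(interpSet)
  jump <- 0
  if (length(retained) >= nInterp + 2) {
    tailKs <- nInterp:length(retained)
    nerrs <- vapply(tailKs, function(k)
      oobError(X, y, retained[seq_len(k)], ntree,
               deriveSeed(seed, paste0("noise", k)), nFor = nFor), 1)
    jump <- mean(abs(diff(nerrs)))
  }
  current <- character(0)
  # baseline: error of the trivial majority-class predictor
  currErr <- 1 - max(table(y)) / length(y)
  for (f in interpSet) {
    cand <- c(current, f)
    e <- oobError(X, y, cand, ntree, deriveSeed(seed, paste0("pred_", f)),
                  nFor = nFor)
    if (currErr - e > jump || !length(current)) {
      current <- cand
      currErr <- e
    }
  }
  current
}

#' Three-step feature selection
#'
#' Runs ranking, threshold, interpretation and prediction steps on the
#' training set and returns the nested results. All randomness derives from
#' one master seed recorded in the result.
#'
#' @param X normalized training descriptor matrix.
#' @param y ACT/INA labels.
#' @param nRuns ranking forests (default 25).
#' @param ntreeRank trees per ranking forest (default 500).
#' @param nForInterp forests per nested-model size (default 10).
#' @param ntree trees for interpretation/prediction forests (default 100).
#' @param seed master seed.
#' @return a \linkS4class{SelectionResult}.
#' @export
selectFeatures <- function(X, y, nRuns = 25, ntreeRank = 500,
                           nForInterp = 10, ntree = 100, seed = 1) {
  rk <- importanceRanking(X, y, nRuns = nRuns, ntree = ntreeRank, seed = seed)
  thr <- thresholdStep(rk)
  if (!length(thr)) {
    return(new("SelectionResult", ranking = rk, thresholdKept = character(0),
               interpretationKept = character(0), predictionKept = character(0),
               params = list(nRuns = nRuns, ntreeRank = ntreeRank,
                             nForInterp = nForInterp, ntree = ntree,
                             seed = seed)))
  }
  interp <- interpretationStep(thr, X, y, nFor = nForInterp, ntree = ntree,
                               seed = seed)
  pred <- predictionStep(interp, thr, X, y, ntree = ntree, nFor = nForInterp,
                         seed = seed)
  new("SelectionResult", ranking = rk, thresholdKept = thr,
      interpretationKept = interp, predictionKept = pred,
      params = list(nRuns = nRuns, ntreeRank = ntreeRank,
                    nForInterp = nForInterp, ntree = ntree, seed = seed))
}

#' Serialize a selection result to JSON
#'
#' @param x a \linkS4class{SelectionResult}.
#' @param path output JSON path.
#' @export
writeSelectionResult <- function(x, path) {
  stopifnot(is(x, "SelectionResult"))
  jsonlite::write_json(list(ranking = x@ranking,
                            threshold_kept = x@thresholdKept,
                            interpretation_kept = x@interpretationKept,
                            prediction_kept = x@predictionKept,
                            params = x@params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
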