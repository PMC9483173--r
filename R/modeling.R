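# The six classifier families behind one fit/predict surface, hyperparameter
# search with stratified 5-fold cross-validation, and the abstaining
# consensus. Model selection uses mean cross-validated balanced accuracy.

.algorithms <- c("BRF", "RF", "KNN", "GB", "XGB", "MLP", "SVM")

fitModel <- function(algorithm, X, y, params, seed = 1) {
  y <- asClassFactor(y)
  X <- as.matrix(X)
  p <- ncol(X)
  obj <- switch(algorithm,
    RF = withSeed(seed, randomForest::randomForest(
      X, y, ntree = params$ntree %||% 500,
      mtry = max(1L, floor((params$mtryMult %||% 1) * sqrt(p))))),
    BRF = {
      # balanced random forest: every tree trains on an equal-size
      # per-class bootstrap drawn by balancedBootstrap()
      ntree <- params$ntree %||% 500
      mtry <- max(1L, floor((params$mtryMult %||% 1) * sqrt(p)))
      samples <- balancedBootstrap(y, ntree, seed = deriveSeed(seed, "brf"))
      trees <- lapply(seq_len(ntree), function(t) {
        idx <- samples[[t]]
        withSeed(deriveSeed(seed, paste0("tree", t)),
          randomForest::randomForest(X[idx, , drop = FALSE], y[idx],
                                     ntree = 1, mtry = mtry,
                                     replace = FALSE, sampsize = length(idx)))
      })
      do.call(randomForest::combine, trees)
    },
    KNN = list(train = X, cl = y, k = params$k %||% 5,
               seed = deriveSeed(seed, "knn")),
    GB = ,
    XGB = withSeed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = params$eta %||% 0.1,
                    max_depth = params$max_depth %||% 3,
                    subsample = params$subsample %||% 1,
                    colsample_bytree = params$colsample %||% 1,
                    lambda = params$lambda %||% 1,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "ACT")),
      nrounds = params$nrounds %||% 100, verbose = 0)),
    MLP = withSeed(seed, nnet::nnet(
      x = X, y = as.numeric(y == "ACT"), size = params$size %||% 8,
      decay = params$decay %||% 1e-3, maxit = params$maxit %||% 200,
      entropy = TRUE, trace = FALSE, MaxNWts = 50000)),
    SVM = withSeed(seed, e1071::svm(
      x = X, y = y, kernel = "radial",
      cost = params$cost %||% 1, gamma = params$gamma %||% (1 / p),
      probability = TRUE)),
    stop("unknown algorithm: ", algorithm))
  list(algorithm = algorithm, fit = obj, features = colnames(X))
}

predictModelProb <- function(model, X) {
  X <- as.matrix(X)
  switch(model$algorithm,
    RF = ,
    BRF = predict(model$fit, X, type = "prob")[, "ACT"],
    KNN = {
      withSeed(model$fit$seed, {
        pr <- class::knn(model$fit$train, X, model$fit$cl,
                         k = model$fit$k, prob = TRUE)
        win <- attr(pr, "prob")
        ifelse(pr == "ACT", win, 1 - win)
      })
    },
    GB = ,
    XGB = predict(model$fit, xgboost::xgb.DMatrix(X)),
    MLP = as.numeric(predict(model$fit, X, type = "raw")),
    SVM = {
      pr <- predict(model$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "ACT"]
    })
}

#' Default hyperparameter search spaces
#'
#' Literature-standard desk-scale grids per family. SVM and XGB spaces are
#' larger and are explored by budgeted random search instead of
#' exhaustively (see \code{\link{tuneAndTrain}}).
#'
#' @param algorithm one of BRF, RF, KNN, GB, XGB, MLP, SVM.
#' @param p number of features (scales kernel widths and mtry).
#' @return data.frame, one row per candidate configuration.
#' @export
defaultSearchSpace <- function(algorithm, p) {
  switch(algorithm,
    BRF = ,
    RF = expand.grid(ntree = c(100, 500), mtryMult = c(0.5, 1, 2)),
    KNN = data.frame(k = c(3, 5, 7, 9)),
    GB = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1, 0.3),
                     max_depth = c(2, 3)),
    XGB = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1, 0.3),
                      max_depth = c(2, 4, 6), subsample = c(0.7, 1),
                      colsample = c(0.7, 1), lambda = c(0, 1, 10)),
    MLP = expand.grid(size = c(8, 32), decay = c(1e-3, 1e-2)),
    SVM = expand.grid(cost = 10^(-1:2), gamma = (1 / p) * 10^seq(-1, 1, 0.5)),
    stop("unknown algorithm: ", algorithm))
}

#' Stratified k-fold cross-validation of one configuration
#'
#' Folds are stratified so both classes appear in every fold (class ratio
#' preserved within one compound per fold) and form a partition of the rows.
#'
#' @param algorithm family id.
#' @param params hyperparameter list for \code{algorithm}.
#' @param X,y training data.
#' @param k folds (default 5).
#' @param seed seed for folding and fold-model fits.
#' @return list(folds = per-fold data.frame of SE/SP/BA/MCC/AUC,
#'   mean = named means, fold_assignment = integer vector).
#' @export
kfoldCV <- function(algorithm, params, X, y, k = 5, seed = 1) {
  y <- asClassFactor(y)
  if (nrow(X) < k) stop("fewer rows than folds")
  fold <- stratifiedFolds(y, k, seed = deriveSeed(seed, "folds"))
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    m <- fitModel(algorithm, X[tr, , drop = FALSE], y[tr], params,
                  seed = deriveSeed(seed, paste0("cv", f)))
    sc <- predictModelProb(m, X[!tr, , drop = FALSE])
    pred <- ifelse(sc >= 0.5, "ACT", "INA")
    rep <- metricReport(y[!tr], pred, scores = sc)
    data.frame(fold = f, SE = rep$SE, SP = rep$SP, BA = rep$BA,
               MCC = rep$MCC, AUC = rep$AUC)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = colMeans(folds[, c("SE", "SP", "BA", "MCC", "AUC")]),
       fold_assignment = fold)
}

#' Tune and train one classifier family
#'
#' Evaluates candidate hyperparameters by mean balanced accuracy under
#' stratified 5-fold cross-validation. BRF, RF, KNN, GB and MLP use an
#' exhaustive grid; the larger SVM and XGB spaces are explored by a seeded
#' random search capped at \code{budget} configurations. The winner is refit
#' on the full training data.
#'
#' @param algorithm family id (BRF, RF, KNN, GB, XGB, MLP, SVM).
#' @param X normalized, feature-selected training matrix.
#' @param y ACT/INA labels.
#' @param searchSpace optional data.frame overriding the default space.
#' @param budget random-search cap for SVM/XGB (default 10).
#' @param k CV folds (default 5).
#' @param seed master seed.
#' @param threshold potency threshold the labels come from (5 or 6).
#' @param smoteUsed bookkeeping flag stored in the bundle.
#' @param normStats training normalization statistics to store.
#' @param adModel optional \linkS4class{ADModel} to store.
#' @return a \linkS4class{ModelBundle}.
#' @export
tuneAndTrain <- function(algorithm, X, y, searchSpace = NULL, budget = 10,
                         k = 5, seed = 1, threshold = 6, smoteUsed = FALSE,
                         normStats = data.frame(), adModel = NULL) {
  stopifnot(algorithm %in% .algorithms)
  X <- as.matrix(X)
  space <- searchSpace %||% defaultSearchSpace(algorithm, ncol(X))
  if (!nrow(space)) stop("empty hyperparameter space")
  if (algorithm %in% c("SVM", "XGB") && nrow(space) > budget)
    space <- space[withSeed(deriveSeed(seed, "budget"),
                            sort(sample.int(nrow(space), budget))), ,
                   drop = FALSE]
  cvs <- lapply(seq_len(nrow(space)), function(i)
    kfoldCV(algorithm, as.list(space[i, , drop = FALSE]), X, y, k = k,
            seed = deriveSeed(seed, "tune")))
  ba <- vapply(cvs, function(cv) cv$mean[["BA"]], 1)
  best <- which.max(ba)          # ties: first config in fixed grid order
  params <- as.list(space[best, , drop = FALSE])
  final <- fitModel(algorithm, X, y, params, seed = deriveSeed(seed, "final"))
  new("ModelBundle", algorithm = algorithm, model = final,
      hyperparameters = params, selectedFeatures = colnames(X),
      normStats = normStats, smoteUsed = smoteUsed, threshold = threshold,
      cvMetrics = list(folds = cvs[[best]]$folds, mean = cvs[[best]]$mean),
      ad = adModel, seed = seed)
}

#' Probability of hERG blockade
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param X numeric matrix whose columns match the bundle's selected
#'   features (already normalized with the bundle's statistics).
#' @return numeric scores in [0, 1]; the class call is score >= 0.5.
#' @export
predictProba <- function(bundle, X) {
  stopifnot(is(bundle, "ModelBundle"))
  X <- as.matrix(X)
  miss <- setdiff(bundle@selectedFeatures, colnames(X))
  extra <- setdiff(colnames(X), bundle@selectedFeatures)
  if (length(miss) || (length(extra) && is.null(miss)))
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "),
         "; extra: ", paste(extra, collapse = ", "))
  if (length(miss))
    stop("feature mismatch; missing: ", paste(miss, collapse = ", "))
  X <- X[, bundle@selectedFeatures, drop = FALSE]
  unname(predictModelProb(bundle@model, X))
}

#' Build a consensus model
#'
#' @param members list of 2-3 \linkS4class{ModelBundle}s sharing threshold
#'   and feature space.
#' @param rule "unanimity" (default; a label is emitted only on full
#'   agreement, otherwise the consensus abstains) or "majority" (3 members).
#' @return a \linkS4class{ConsensusModel}.
#' @export
consensusModel <- function(members, rule = "unanimity") {
  if (rule == "majority" && length(members) != 3)
    stop("majority rule needs exactly 3 members")
  new("ConsensusModel", members = members, rule = rule)
}

#' Consensus prediction with abstention
#'
#' Each member votes with its 0.5-cutoff class call; under the unanimity
#' rule a class is emitted only when all members concord, and discordant
#' rows are ABSTAIN. The consensus score (used for AUC) is the arithmetic
#' mean of the member probabilities.
#'
#' @param consensus a \linkS4class{ConsensusModel}.
#' @param X prepared feature matrix (see \code{\link{predictProba}}).
#' @return data.frame(label, score, plus one vote column per member);
#'   predicted rows + abstained rows = total rows.
#' @export
consensusPredict <- function(consensus, X) {
  stopifnot(is(consensus, "ConsensusModel"))
  probs <- vapply(consensus@members, function(m) predictProba(m, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) probs <- matrix(probs, nrow = 1)
  votes <- ifelse(probs >= 0.5, "ACT", "INA")
  nAct <- rowSums(votes == "ACT")
  k <- length(consensus@members)
  label <- if (consensus@rule == "unanimity")
    ifelse(nAct == k, "ACT", ifelse(nAct == 0, "INA", "ABSTAIN"))
  else ifelse(nAct * 2 > k, "ACT", "INA")
  out <- data.frame(label = label, score = rowMeans(probs))
  vt <- as.data.frame(votes)
  names(vt) <- paste0("vote_", vapply(consensus@members,
                                      function(m) m@algorithm, ""),
                      "_", seq_len(k))
  cbind(out, vt)
}
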