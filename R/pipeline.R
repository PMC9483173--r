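# End-to-end orchestration: curate -> descriptors -> split -> select ->
# (SMOTE) -> tune/train -> applicability domain -> evaluate -> consensus,
# with on-disk model bundles and a reproducibility manifest.

.bundleFormatVersion <- "1"

#' Save / load a trained model bundle
#'
#' A bundle directory holds the serialized fitted model plus a JSON metadata
#' file (algorithm, hyperparameters, selected features, normalization
#' statistics, seed, threshold, format version) so a run is reproducible and
#' inspectable without deserializing the model.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param dir bundle directory (created if needed).
#' @return \code{loadModelBundle} returns the \linkS4class{ModelBundle}.
#' @export
saveModelBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "ModelBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  meta <- list(format_version = .bundleFormatVersion,
               algorithm = bundle@algorithm,
               hyperparameters = bundle@hyperparameters,
               selected_features = bundle@selectedFeatures,
               norm_stats = bundle@normStats,
               smote_used = bundle@smoteUsed,
               threshold = bundle@threshold,
               cv_mean = as.list(bundle@cvMetrics$mean),
               seed = bundle@seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  f <- file.path(dir, "bundle.rds")
  if (!file.exists(f)) stop("no bundle at ", dir)
  readRDS(f)
}

normalizeConfig <- function(config) {
  defaults <- list(threshold = 6, algorithms = c("BRF", "KNN", "SVM"),
                   smote = TRUE, allowBrfSmote = FALSE, fraction = 0.8,
                   select = TRUE, seed = 1, budget = 10, cvFolds = 5,
                   smoteK = 5, consensusSize = 2, backend = "obgraph2d",
                   selection = list(), searchSpaces = list())
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  modifyList(defaults, config)
}

prepareInput <- function(config, log) {
  if (!is.null(config$descriptors)) {
    m <- config$descriptors
    if (is.character(m)) m <- readDescriptorMatrix(m)
    if (is.matrix(m)) m <- new("DescriptorMatrix", values = m,
                               normStats = data.frame(),
                               backend = "precomputed")
    labels <- config$labels
    if (is.null(labels)) stop("descriptor input needs labels")
    if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
      lf <- read.csv(labels, stringsAsFactors = FALSE)
      labels <- setNames(lf$label, lf$compound_id)[rownames(m@values)]
    }
    log("input", sprintf("descriptor matrix: %d x %d", nrow(m@values),
                         ncol(m@values)))
    list(matrix = m, labels = asClassFactor(labels),
         ids = rownames(m@values), curated = NULL, hasSmiles = FALSE)
  } else if (!is.null(config$activity)) {
    records <- config$activity
    if (is.character(records)) records <- readActivityTable(
      records, columnMap = config$columnMap)
    curated <- curateActivityData(records)
    cp <- compounds(curated)
    log("curate", sprintf("%d compounds curated, %d records rejected",
                          nrow(cp), nrow(rejections(curated))))
    labCol <- if (config$threshold == 6) cp$label_t6 else cp$label_t5
    m <- computeDescriptors(cp$canonical_smiles, backend = config$backend)
    keep <- match(rownames(m@values), cp$canonical_smiles)
    log("descriptors", sprintf("%d x %d raw descriptors", nrow(m@values),
                               ncol(m@values)))
    list(matrix = m, labels = asClassFactor(labCol[keep]),
         ids = rownames(m@values), curated = curated, hasSmiles = TRUE)
  } else stop("config needs either $activity or $descriptors input")
}

# per-class seeded random split preserving the class ratio; used when no
# structures (hence no fingerprints) are available for MaxMin picking
stratifiedRandomSplit <- function(ids, labels, fraction, seed) {
  labels <- asClassFactor(labels)
  trainIds <- character(0)
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      k <- floor(fraction * length(idx) + 0.5)
      k <- min(max(k, 1L), length(idx) - 1L)
      trainIds <- c(trainIds, ids[sample(idx, k)])
    }
  })
  new("DatasetSplit", trainIds = trainIds, validIds = setdiff(ids, trainIds),
      fraction = fraction, perClass = TRUE)
}

#' Run the full training pipeline
#'
#' Executes curation, descriptor computation, per-class diversity splitting,
#' normalization, three-step feature selection (training set only), SMOTE
#' oversampling (training set only; never combined with BRF unless
#' explicitly allowed), hyperparameter tuning with stratified 5-fold CV,
#' applicability-domain fitting (on original training rows, pre-SMOTE), and
#' validation-set evaluation restricted to in-domain compounds; finally
#' builds a consensus of the top-performing members ranked by validation BA
#' then AUC.
#'
#' @param config list or YAML path. Inputs: \code{activity} (raw table,
#'   data.frame or file) or \code{descriptors} (+ \code{labels}). Keys:
#'   \code{threshold} (6), \code{algorithms} (BRF, KNN, SVM), \code{smote}
#'   (TRUE), \code{fraction} (0.8), \code{select} (TRUE), \code{selection}
#'   (parameter list for \code{\link{selectFeatures}}), \code{budget},
#'   \code{cvFolds}, \code{smoteK}, \code{consensusSize}, \code{seed},
#'   \code{outDir} (optional: writes artifacts).
#' @return (invisibly) list with curated set, split, selection, bundles,
#'   validation metric table, consensus model and its report.
#' @export
runTrainingPipeline <- function(config) {
  config <- normalizeConfig(config)
  seed <- config$seed
  stages <- character(0)
  log <- function(stage, msg) {
    stages <<- c(stages, stage)
    message("[", stage, "] ", msg)
  }
  onFail <- function(stage, e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         "; completed stages: ", paste(stages, collapse = " -> "))

  inp <- tryCatch(prepareInput(config, log), error = function(e)
    onFail("input", e))
  m <- inp$matrix; labels <- inp$labels; ids <- inp$ids

  pr <- tryCatch(pruneDescriptors(m), error = function(e) onFail("prune", e))
  m <- pr$matrix
  log("prune", sprintf("%d descriptors retained (%d removed)",
                       ncol(m@values), nrow(pr$removed)))

  split <- tryCatch({
    if (inp$hasSmiles) {
      fp <- morganFingerprint(ids)
      maxMinSplit(fp, ids, labels, fraction = config$fraction,
                  seed = deriveSeed(seed, "split"))
    } else
      stratifiedRandomSplit(ids, labels, config$fraction,
                            deriveSeed(seed, "split"))
  }, error = function(e) onFail("split", e))
  log("split", sprintf("%d train / %d valid", length(trainIds(split)),
                       length(validIds(split))))

  tr <- match(trainIds(split), ids); va <- match(validIds(split), ids)
  yTr <- labels[tr]; yVa <- labels[va]
  mTr <- normalizeDescriptors(new("DescriptorMatrix",
                                  values = m@values[tr, , drop = FALSE],
                                  normStats = data.frame(),
                                  backend = m@backend))
  stats <- normStats(mTr)
  mVa <- normalizeDescriptors(new("DescriptorMatrix",
                                  values = m@values[va, , drop = FALSE],
                                  normStats = data.frame(),
                                  backend = m@backend), stats = stats)
  XTr <- descriptorValues(mTr); XVa <- descriptorValues(mVa)

  selection <- NULL
  feats <- colnames(XTr)
  if (isTRUE(config$select)) {
    selection <- tryCatch(do.call(selectFeatures, c(
      list(X = XTr, y = yTr, seed = deriveSeed(seed, "select")),
      config$selection)), error = function(e) onFail("select", e))
    if (length(selectedFeatures(selection))) {
      feats <- selectedFeatures(selection)
    } else warning("feature selection kept nothing; using all descriptors")
    log("select", sprintf("%d features selected", length(feats)))
  }
  XTrS <- XTr[, feats, drop = FALSE]; XVaS <- XVa[, feats, drop = FALSE]

  ad <- tryCatch(fitAD(XTrS), error = function(e) onFail("ad", e))
  log("ad", sprintf("leverage threshold 3p/n = %.4f", adThreshold(ad)))

  aug <- NULL
  runs <- data.frame(algorithm = config$algorithms, stringsAsFactors = FALSE)
  runs$smote <- vapply(runs$algorithm, function(a) {
    isTRUE(config$smote) && (a != "BRF" || isTRUE(config$allowBrfSmote))
  }, TRUE)
  if (any(runs$smote)) {
    aug <- tryCatch(smote(XTrS, yTr, k = config$smoteK,
                          seed = deriveSeed(seed, "smote")),
                    error = function(e) onFail("smote", e))
    log("smote", sprintf("%d synthetic rows -> 1:1", sum(aug@syntheticMask)))
  }

  bundles <- list(); metricTab <- NULL
  for (i in seq_len(nrow(runs))) {
    alg <- runs$algorithm[i]; useSmote <- runs$smote[i]
    Xfit <- if (useSmote) aug@X else XTrS
    yfit <- if (useSmote) aug@y else yTr
    b <- tryCatch(tuneAndTrain(
      alg, Xfit, yfit, searchSpace = config$searchSpaces[[alg]],
      budget = config$budget, k = config$cvFolds,
      seed = deriveSeed(seed, paste0("train_", alg)),
      threshold = config$threshold, smoteUsed = useSmote,
      normStats = stats[stats$name %in% feats, , drop = FALSE],
      adModel = ad), error = function(e) onFail(paste0("train_", alg), e))
    name <- paste0(if (useSmote) "S" else "", alg)
    bundles[[name]] <- b
    inAD <- inDomain(ad, XVaS)
    sc <- predictProba(b, XVaS[inAD, , drop = FALSE])
    pred <- ifelse(sc >= 0.5, "ACT", "INA")
    rep <- metricReport(yVa[inAD], pred, scores = sc,
                        nOutOfDomain = sum(!inAD))
    metricTab <- rbind(metricTab, metricRow(rep, name))
    log(paste0("train_", alg),
        sprintf("%s: validation BA %.3f (CV BA %.3f)", name, rep$BA,
                b@cvMetrics$mean[["BA"]]))
  }

  consensus <- NULL; consReport <- NULL
  if (length(bundles) >= 2) {
    ord <- order(-metricTab$BA, -metricTab$AUC)
    top <- ord[seq_len(min(config$consensusSize, length(bundles)))]
    consensus <- consensusModel(unname(bundles[top]))
    inAD <- inDomain(ad, XVaS)
    cp <- consensusPredict(consensus, XVaS[inAD, , drop = FALSE])
    keep <- cp$label != "ABSTAIN"
    consReport <- metricReport(yVa[inAD][keep], cp$label[keep],
                               scores = cp$score[keep],
                               nAbstained = sum(!keep),
                               nOutOfDomain = sum(!inAD))
    metricTab <- rbind(metricTab, metricRow(
      consReport, paste0("CONSENSUS(", paste(metricTab$model[top],
                                             collapse = "+"), ")")))
    log("consensus", sprintf("members %s: BA %.3f, coverage %.1f%%",
                             paste(metricTab$model[top], collapse = "+"),
                             consReport$BA, 100 * mean(keep)))
  }

  result <- list(config = config, curated = inp$curated, split = split,
                 selection = selection, features = feats,
                 normStats = stats, smote = aug, ad = ad, bundles = bundles,
                 metrics = metricTab, consensus = consensus,
                 consensusReport = consReport)

  if (!is.null(config$outDir)) {
    out <- config$outDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(inp$curated))
      writeCuratedSet(inp$curated, file.path(out, "curated.csv"))
    writeDescriptorMatrix(m, file.path(out, "descriptors_pruned.csv"))
    writeSplitManifest(split, file.path(out, "split.csv"))
    if (!is.null(selection))
      writeSelectionResult(selection, file.path(out, "selection.json"))
    write.csv(metricTab, file.path(out, "metrics.csv"), row.names = FALSE)
    for (nm in names(bundles))
      saveModelBundle(bundles[[nm]], file.path(out, "bundles", nm))
    manifest <- list(seed = seed, threshold = config$threshold,
                     algorithms = runs, features = feats,
                     stages = stages, format_version = .bundleFormatVersion)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    log("write", paste("artifacts in", out))
  }
  invisible(result)
}

#' Predict hERG blockade for new compounds
#'
#' Standardizes the input structures, computes descriptors with the bundles'
#' backend (or takes a precomputed descriptor matrix), applies the stored
#' training normalization, restricts to each bundle's selected features, and
#' reports per-model class calls, the consensus call (ABSTAIN on
#' discordance), the mean probability score, and the applicability-domain
#' flag. Rows whose SMILES cannot be standardized are flagged and skipped,
#' the rest are processed.
#'
#' @param smiles character vector of SMILES, or a path to a one-column CSV
#'   (header required) for batch mode.
#' @param bundles a directory written by \code{\link{runTrainingPipeline}}
#'   (its \code{bundles/} subdirectories are loaded), a list of
#'   \linkS4class{ModelBundle}s, or a single bundle.
#' @param descriptors optional precomputed \linkS4class{DescriptorMatrix}
#'   (or CSV path) keyed by the input SMILES, replacing on-the-fly
#'   computation.
#' @return data.frame: input and canonical SMILES, status, one call column
#'   per member model, consensus label, consensus score, applicability
#'   domain flag, and the potency threshold. One row per input row.
#' @export
predictHerg <- function(smiles, bundles, descriptors = NULL) {
  if (length(smiles) == 1 && file.exists(smiles) &&
      grepl("\\.(csv|smi|txt)$", smiles, ignore.case = TRUE)) {
    df <- read.csv(smiles, stringsAsFactors = FALSE)
    smiles <- as.character(df[[1]])
  }
  if (is(bundles, "ModelBundle")) bundles <- list(bundles)
  if (is.character(bundles)) {
    root <- if (dir.exists(file.path(bundles, "bundles")))
      file.path(bundles, "bundles") else bundles
    dirs <- list.dirs(root, recursive = FALSE)
    if (!length(dirs)) stop("no model bundles under ", bundles)
    bundles <- setNames(lapply(dirs, loadModelBundle), basename(dirs))
  }
  stopifnot(length(bundles) >= 1)
  thr <- unique(vapply(bundles, function(b) b@threshold, 1))
  if (length(thr) != 1)
    stop("bundles mix thresholds; predict per threshold block")
  backend <- "obgraph2d"

  std <- standardizeStructures(smiles)
  out <- data.frame(input_smiles = smiles,
                    canonical_smiles = std$canonical_smiles,
                    status = ifelse(std$status == "OK", "OK",
                                    paste0("REJECTED:", std$reason)))
  ok <- which(std$status == "OK")
  memberCols <- paste0("call_", names(bundles) %||%
                         vapply(bundles, function(b) b@algorithm, ""))
  for (cn in memberCols) out[[cn]] <- NA_character_
  out$consensus <- NA_character_
  out$consensus_score <- NA_real_
  out$applicability_domain <- NA
  out$threshold <- thr
  if (!length(ok)) return(out)

  can <- std$canonical_smiles[ok]
  if (is.null(descriptors)) {
    m <- computeDescriptors(can, backend = backend)
  } else {
    m <- if (is.character(descriptors)) readDescriptorMatrix(descriptors)
    else descriptors
    missing <- setdiff(can, rownames(m@values))
    if (length(missing))
      stop("precomputed descriptors lack compounds: ",
           paste(head(missing, 3), collapse = ", "))
    m <- new("DescriptorMatrix", values = m@values[can, , drop = FALSE],
             normStats = data.frame(), backend = m@backend)
  }
  present <- match(rownames(m@values), can)
  rowsOk <- ok[present]

  probs <- matrix(NA_real_, length(rowsOk), length(bundles))
  inAD <- rep(TRUE, length(rowsOk))
  for (j in seq_along(bundles)) {
    b <- bundles[[j]]
    st <- b@normStats
    mz <- normalizeDescriptors(new("DescriptorMatrix",
      values = m@values[, st$name, drop = FALSE],
      normStats = data.frame(), backend = m@backend), stats = st)
    Xb <- descriptorValues(mz)[, b@selectedFeatures, drop = FALSE]
    probs[, j] <- predictProba(b, Xb)
    if (!is.null(b@ad)) inAD <- inAD & inDomain(b@ad, Xb)
    out[rowsOk, memberCols[j]] <- ifelse(probs[, j] >= 0.5, "ACT", "INA")
  }
  nAct <- rowSums(probs >= 0.5)
  out$consensus[rowsOk] <- ifelse(nAct == ncol(probs), "ACT",
                                  ifelse(nAct == 0, "INA", "ABSTAIN"))
  out$consensus_score[rowsOk] <- rowMeans(probs)
  out$applicability_domain[rowsOk] <- inAD
  out
}
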