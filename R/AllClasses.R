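#' @import methods
NULL

#' Curated compound set
#'
#' Container for the output of activity-data curation: one row per unique
#' QSAR-ready structure, with the aggregated potency (pIC50), the replicate
#' spread sigma, and the class label at both potency thresholds
#' (pIC50 = 6, i.e. IC50 <= 1 uM, and pIC50 = 5, i.e. IC50 <= 10 uM).
#'
#' @slot compounds data.frame with columns \code{canonical_smiles},
#'   \code{pIC50} (NA only for comment-labeled inactives), \code{sigma},
#'   \code{n_records}, \code{label_t6}, \code{label_t5}.
#' @slot rejections data.frame log of rejected records (reason codes).
#' @export
setClass("CuratedSet",
  representation(compounds = "data.frame", rejections = "data.frame"),
  validity = function(object) {
    cp <- object@compounds
    need <- c("canonical_smiles", "pIC50", "sigma", "n_records",
              "label_t6", "label_t5")
    if (!all(need %in% names(cp))) return("missing compound columns")
    if (anyDuplicated(cp$canonical_smiles)) return("duplicate canonical SMILES")
    if (any(!is.na(cp$sigma) & cp$sigma > 2)) return("sigma > 2 compound retained")
    if (!all(cp$label_t6 %in% .classLevels) || !all(cp$label_t5 %in% .classLevels))
      return("labels must be ACT/INA")
    TRUE
  })

#' Descriptor matrix
#'
#' Compounds-by-descriptors numeric matrix plus, once fitted, the per-column
#' normalization statistics (mean, sd) that external sets must reuse.
#'
#' @slot values numeric matrix, rows = compounds (rownames = canonical SMILES).
#' @slot normStats data.frame(name, mean, sd) or empty if unnormalized.
#' @slot backend character id of the descriptor backend that produced it.
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", normStats = "data.frame",
                 backend = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      return("descriptor names must be present and unique")
    ns <- object@normStats
    if (nrow(ns) && !all(c("name", "mean", "sd") %in% names(ns)))
      return("normStats needs name/mean/sd")
    TRUE
  })

#' Train/validation split
#'
#' @slot trainIds,validIds disjoint character vectors of compound ids.
#' @slot fraction training fraction in (0, 1).
#' @slot perClass whether picking ran independently within each class.
#' @export
setClass("DatasetSplit",
  representation(trainIds = "character", validIds = "character",
                 fraction = "numeric", perClass = "logical"),
  validity = function(object) {
    if (length(intersect(object@trainIds, object@validIds)))
      return("train and valid overlap")
    if (object@fraction <= 0 || object@fraction >= 1)
      return("fraction must be in (0,1)")
    TRUE
  })

#' Three-step feature-selection result
#'
#' @slot ranking data.frame(name, mean_importance, sd_importance), descending.
#' @slot thresholdKept,interpretationKept,predictionKept nested feature lists.
#' @slot params list of run parameters including the master seed.
#' @export
setClass("SelectionResult",
  representation(ranking = "data.frame", thresholdKept = "character",
                 interpretationKept = "character", predictionKept = "character",
                 params = "list"),
  validity = function(object) {
    if (!all(object@predictionKept %in% object@interpretationKept))
      return("prediction set not nested in interpretation set")
    if (!all(object@interpretationKept %in% object@thresholdKept))
      return("interpretation set not nested in threshold set")
    TRUE
  })

#' SMOTE-augmented training set
#'
#' @slot X numeric matrix (original rows first, then synthetic rows).
#' @slot y factor INA/ACT for every row of X.
#' @slot syntheticMask TRUE for rows created by interpolation.
#' @slot parentPairs data.frame(sample, neighbor, weight) per synthetic row.
#' @export
setClass("AugmentedTrainingSet",
  representation(X = "matrix", y = "factor", syntheticMask = "logical",
                 parentPairs = "data.frame"),
  validity = function(object) {
    tab <- table(object@y)
    if (length(tab) == 2 && tab[1] != tab[2]) return("classes not 1:1")
    if (length(object@syntheticMask) != nrow(object@X))
      return("mask length mismatch")
    TRUE
  })

#' Leverage-based applicability domain
#'
#' Stores (X'X)^-1 of the training descriptor matrix; a query compound with
#' leverage h = x' (X'X)^-1 x above 3p/n is outside the domain.
#'
#' @slot gramInverse p x p matrix (pseudoinverse when X'X is singular).
#' @slot p,n descriptor and training-compound counts.
#' @slot threshold 3 * p / n.
#' @export
setClass("ADModel",
  representation(gramInverse = "matrix", p = "numeric", n = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@threshold, 3 * object@p / object@n)))
      return("threshold must equal 3p/n")
    if (max(abs(object@gramInverse - t(object@gramInverse))) > 1e-10)
      return("gram inverse not symmetric")
    TRUE
  })

#' Fitted classifier bundle
#'
#' @slot algorithm one of BRF, RF, KNN, GB, XGB, MLP, SVM.
#' @slot model fitted model object (backend-specific).
#' @slot hyperparameters winning hyperparameter list.
#' @slot selectedFeatures feature names the model consumes, in order.
#' @slot normStats training normalization statistics (name, mean, sd).
#' @slot smoteUsed whether training data were SMOTE-augmented.
#' @slot threshold potency threshold (5 or 6) the labels were derived at.
#' @slot cvMetrics per-fold and mean cross-validation metrics.
#' @slot ad applicability-domain model fitted on the training matrix.
#' @slot seed master seed of the training run.
#' @export
setClass("ModelBundle",
  representation(algorithm = "character", model = "ANY",
                 hyperparameters = "list", selectedFeatures = "character",
                 normStats = "data.frame", smoteUsed = "logical",
                 threshold = "numeric", cvMetrics = "list", ad = "ANY",
                 seed = "numeric"),
  validity = function(object) {
    if (!object@algorithm %in% c("BRF", "RF", "KNN", "GB", "XGB", "MLP", "SVM"))
      return("unknown algorithm id")
    if (!object@threshold %in% c(5, 6)) return("threshold must be 5 or 6")
    TRUE
  })

#' Consensus of trained classifiers
#'
#' Emits a class only when all member models agree; otherwise abstains.
#'
#' @slot members list of 2-3 \linkS4class{ModelBundle}s sharing a threshold.
#' @slot rule "unanimity" (default) or "majority" (3 members only).
#' @export
setClass("ConsensusModel",
  representation(members = "list", rule = "character"),
  validity = function(object) {
    if (length(object@members) < 2 || length(object@members) > 3)
      return("consensus needs 2-3 members")
    thr <- vapply(object@members, function(m) m@threshold, 1)
    if (length(unique(thr)) != 1) return("members disagree on threshold")
    if (!object@rule %in% c("unanimity", "majority")) return("unknown rule")
    TRUE
  })

setMethod("show", "CuratedSet", function(object) {
  cp <- object@compounds
  cat("CuratedSet:", nrow(cp), "compounds,",
      nrow(object@rejections), "rejected records\n")
  if (nrow(cp)) {
    cat("  ACT/INA at pIC50>=6:", sum(cp$label_t6 == "ACT"), "/",
        sum(cp$label_t6 == "INA"), "\n")
    cat("  ACT/INA at pIC50>=5:", sum(cp$label_t5 == "ACT"), "/",
        sum(cp$label_t5 == "INA"), "\n")
  }
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat("DescriptorMatrix:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors [", object@backend, "]",
      if (nrow(object@normStats)) "(normalized)" else "(raw)", "\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d valid (fraction %.2f%s)\n",
              length(object@trainIds), length(object@validIds),
              object@fraction,
              if (object@perClass) ", per class" else ""))
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", nrow(object@ranking), "ranked ->",
      length(object@thresholdKept), "threshold ->",
      length(object@interpretationKept), "interpretation ->",
      length(object@predictionKept), "prediction\n")
})

setMethod("show", "ADModel", function(object) {
  cat(sprintf("ADModel: p = %d, n = %d, leverage threshold 3p/n = %.4f\n",
              object@p, object@n, object@threshold))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle <%s> threshold %d, %d features%s\n",
              object@algorithm, object@threshold,
              length(object@selectedFeatures),
              if (object@smoteUsed) ", SMOTE" else ""))
})

setMethod("show", "ConsensusModel", function(object) {
  cat("ConsensusModel:", paste(vapply(object@members, function(m)
    m@algorithm, ""), collapse = " + "), "| rule:", object@rule, "\n")
})

# ---- accessors ----

#' Accessors for workflow objects
#'
#' Small exported accessors so user code never touches slots directly.
#'
#' @param x a workflow object.
#' @return the requested component.
#' @name accessors
#' @export
compounds <- function(x) { stopifnot(is(x, "CuratedSet")); x@compounds }

#' @rdname accessors
#' @export
rejections <- function(x) { stopifnot(is(x, "CuratedSet")); x@rejections }

#' @rdname accessors
#' @export
descriptorValues <- function(x) { stopifnot(is(x, "DescriptorMatrix")); x@values }

#' @rdname accessors
#' @export
normStats <- function(x) {
  if (is(x, "DescriptorMatrix")) return(x@normStats)
  if (is(x, "ModelBundle")) return(x@normStats)
  stop("no normalization statistics in a ", class(x))
}

#' @rdname accessors
#' @export
trainIds <- function(x) { stopifnot(is(x, "DatasetSplit")); x@trainIds }

#' @rdname accessors
#' @export
validIds <- function(x) { stopifnot(is(x, "DatasetSplit")); x@validIds }

#' @rdname accessors
#' @export
selectedFeatures <- function(x) {
  if (is(x, "SelectionResult")) return(x@predictionKept)
  if (is(x, "ModelBundle")) return(x@selectedFeatures)
  stop("no selected features in a ", class(x))
}

#' @rdname accessors
#' @export
adThreshold <- function(x) { stopifnot(is(x, "ADModel")); x@threshold }
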