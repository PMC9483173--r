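# Confusion-matrix statistics (Cooper statistics SE/SP/BA, MCC) and the
# rank-based ROC AUC. ACT (blocker) is the positive class throughout.

#' Confusion counts
#'
#' @param labels true ACT/INA labels (abstained rows excluded upstream).
#' @param predictions predicted ACT/INA labels.
#' @return list(TP, FP, TN, FN).
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  labels <- asClassFactor(labels); predictions <- asClassFactor(predictions)
  list(TP = sum(labels == "ACT" & predictions == "ACT"),
       FP = sum(labels == "INA" & predictions == "ACT"),
       TN = sum(labels == "INA" & predictions == "INA"),
       FN = sum(labels == "ACT" & predictions == "INA"))
}

#' Cooper statistics
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), and balanced
#' accuracy BA = (SE+SP)/2.
#'
#' @param counts list/row with TP, FP, TN, FN.
#' @return list(SE, SP, BA).
#' @export
cooperStats <- function(counts) {
  with(counts, {
    if (TP + FN == 0 || TN + FP == 0)
      stop("undefined metric: one class is empty")
    SE <- TP / (TP + FN); SP <- TN / (TN + FP)
    list(SE = SE, SP = SP, BA = (SE + SP) / 2)
  })
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), computed in
#' floating point to avoid integer overflow; defined as 0 when any marginal
#' is zero.
#'
#' @param counts list/row with TP, FP, TN, FN.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC AUC (rank formula)
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, with ties counted one half. Equivalent
#' to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric scores (higher = more likely ACT).
#' @param labels true ACT/INA labels; both classes required.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  labels <- asClassFactor(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- labels == "ACT"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Full metric report
#'
#' @param labels,predictions as \code{\link{confusionCounts}}.
#' @param scores optional probability scores for AUC.
#' @param nAbstained,nOutOfDomain bookkeeping counts for rows excluded
#'   upstream (consensus abstentions, applicability-domain exclusions).
#' @return list with SE, SP, BA, MCC, AUC (NA without scores), counts, and
#'   the exclusion bookkeeping.
#' @export
metricReport <- function(labels, predictions, scores = NULL,
                         nAbstained = 0L, nOutOfDomain = 0L) {
  counts <- confusionCounts(labels, predictions)
  cs <- cooperStats(counts)
  list(SE = cs$SE, SP = cs$SP, BA = cs$BA, MCC = mcc(counts),
       AUC = if (is.null(scores)) NA_real_ else aucScore(scores, labels),
       counts = counts, n_abstained = nAbstained,
       n_out_of_domain = nOutOfDomain)
}

# one metric report -> data.frame row in the table column order
metricRow <- function(report, label = "") {
  data.frame(model = label,
             BA = report$BA, SE = report$SE, SP = report$SP,
             MCC = report$MCC, AUC = report$AUC,
             TP = report$counts$TP, FP = report$counts$FP,
             TN = report$counts$TN, FN = report$counts$FN,
             n_abstained = report$n_abstained,
             n_out_of_domain = report$n_out_of_domain)
}
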