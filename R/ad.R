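# Leverage-based applicability domain. The leverage of a query row x against
# the training matrix X is h = x' (X'X)^-1 x (a diagonal element of the hat
# matrix when x is a training row); compounds with h > 3p/n are flagged as
# structurally outside the training space.

#' Fit the applicability-domain model
#'
#' Computes (X'X)^-1 of the normalized, feature-selected training matrix
#' (Moore-Penrose pseudoinverse when singular) and the leverage cutoff
#' 3p/n, where p is the number of descriptors and n the number of training
#' compounds.
#'
#' @param X numeric training matrix (original rows only; synthetic SMOTE
#'   rows must not be included — the domain describes real chemical space).
#' @return an \linkS4class{ADModel}.
#' @export
fitAD <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  if (n <= p)
    warning("n <= p: X'X is singular; leverage uses the pseudoinverse")
  g <- MASS::ginv(crossprod(X))
  g <- (g + t(g)) / 2
  dimnames(g) <- list(colnames(X), colnames(X))
  new("ADModel", gramInverse = g, p = p, n = n, threshold = 3 * p / n)
}

#' Leverage of query rows
#'
#' @param ad an \linkS4class{ADModel}.
#' @param x numeric vector (length p) or matrix (columns = descriptors).
#' @return numeric leverage value(s), >= 0.
#' @export
leverage <- function(ad, x) {
  stopifnot(is(ad, "ADModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ad@p) stop("dimension mismatch: expected ", ad@p,
                            " descriptors, got ", ncol(x))
  rowSums((x %*% ad@gramInverse) * x)
}

#' Applicability-domain membership
#'
#' TRUE when leverage <= 3p/n (a compound exactly on the cutoff is inside).
#'
#' @inheritParams leverage
#' @return logical vector.
#' @export
inDomain <- function(ad, x) leverage(ad, x) <= ad@threshold
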