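#' @importFrom stats sd predict runif rnorm prcomp cor dist setNames rbinom rpois
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Deterministic sub-seed derivation: every randomized operation draws its own
# seed from the caller's master seed plus a stage tag, so stages can be rerun
# in isolation without perturbing one another. Kept below 2^31.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (cc in utf8ToInt(as.character(tag))) h <- (h * 131 + cc) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# round-half-up (R's round() is round-half-even; reports follow table style)
roundHalfUp <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

# class labels used throughout: ACT = blocker (positive), INA = non-blocker
.classLevels <- c("INA", "ACT")

asClassFactor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), .classLevels)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  factor(y, levels = .classLevels)
}

# stratified k-fold assignment; preserves class ratio within +/-1 per fold
stratifiedFolds <- function(y, k = 5, seed = 1) {
  y <- asClassFactor(y)
  if (length(y) < k) stop("fewer rows than folds")
  fold <- integer(length(y))
  withSeed(seed, {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      if (!length(idx)) next
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  if (any(vapply(split(y, fold), function(f) length(unique(f)), 1L) < 2L))
    stop("degenerate fold with a single class; reduce k or rebalance")
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
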