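# Rational train/validation partitioning: per-class MaxMin diversity picking
# on Morgan fingerprints with Tanimoto distance, plus a PCA coverage check.

#' Morgan (circular) fingerprint
#'
#' ECFP-style circular fingerprint computed on the heavy-atom connection
#' table: each atom starts from an invariant (element, heavy degree, total
#' bond order, ring membership) and neighborhoods are iteratively hashed out
#' to the given radius; every environment identifier sets one bit of a
#' fixed-length vector. Deterministic and canonicalization-invariant (two
#' SMILES of the same standardized molecule give the same bits).
#'
#' @param smiles character vector of standardized SMILES.
#' @param radius neighborhood radius (default 2, ECFP4-like).
#' @param nbits fingerprint length (default 2048).
#' @return logical matrix, one row per compound.
#' @export
morganFingerprint <- function(smiles, radius = 2, nbits = 2048) {
  mols <- parseMolecules(smiles)
  bad <- vapply(mols, is.null, TRUE)
  if (any(bad))
    stop("unparseable SMILES: ", paste(smiles[bad], collapse = ", "))
  elNum <- function(e) match(e, .allowedElements, nomatch = 99L)
  hashInts <- function(v) {
    h <- 7
    for (x in v) h <- (h * 31 + (x %% 2147483647)) %% 2147483647
    h
  }
  fp <- matrix(FALSE, length(smiles), nbits)
  for (i in seq_along(mols)) {
    mol <- mols[[i]]
    nA <- length(mol$elements)
    deg <- tabulate(c(mol$bonds$from, mol$bonds$to), nbins = nA)
    bosum <- numeric(nA)
    if (nrow(mol$bonds)) {
      for (b in seq_len(nrow(mol$bonds))) {
        bosum[mol$bonds$from[b]] <- bosum[mol$bonds$from[b]] + mol$bonds$order[b]
        bosum[mol$bonds$to[b]] <- bosum[mol$bonds$to[b]] + mol$bonds$order[b]
      }
    }
    ring <- ringAtoms(mol)
    nbr <- vector("list", nA)
    if (nrow(mol$bonds)) {
      for (b in seq_len(nrow(mol$bonds))) {
        f <- mol$bonds$from[b]; t <- mol$bonds$to[b]; o <- mol$bonds$order[b]
        nbr[[f]] <- rbind(nbr[[f]], c(t, o))
        nbr[[t]] <- rbind(nbr[[t]], c(f, o))
      }
    }
    ids <- vapply(seq_len(nA), function(a)
      hashInts(c(elNum(mol$elements[a]), deg[a], bosum[a], ring[a])), 1)
    bits <- ids
    for (r in seq_len(radius)) {
      nxt <- numeric(nA)
      for (a in seq_len(nA)) {
        env <- if (is.null(nbr[[a]])) numeric(0) else {
          pairs <- cbind(nbr[[a]][, 2], ids[nbr[[a]][, 1]])
          ord <- order(pairs[, 2], pairs[, 1])
          as.numeric(t(pairs[ord, , drop = FALSE]))
        }
        nxt[a] <- hashInts(c(r, ids[a], env))
      }
      ids <- nxt
      bits <- c(bits, ids)
    }
    fp[i, unique(bits %% nbits) + 1] <- TRUE
  }
  rownames(fp) <- smiles
  fp
}

#' Tanimoto similarity between binary fingerprints
#'
#' |a AND b| / |a OR b|; two all-zero vectors are defined as identical
#' (similarity 1). Distance for diversity picking is 1 - similarity.
#'
#' @param a,b logical/0-1 vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

# all-pairs Tanimoto similarity for a 0/1 matrix (rows = compounds)
tanimotoMatrix <- function(fp) {
  m <- matrix(as.numeric(fp), nrow(fp))
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  un <- outer(pop, pop, "+") - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1))
  sim
}

# greedy MaxMin picking of k items; first pick = max popcount
# (lexicographic tie-break on id); later picks maximize the minimum
# Tanimoto distance to the picked set, same tie-break.
maxMinPick <- function(fp, ids, k, seed = NULL) {
  n <- nrow(fp)
  stopifnot(k >= 1, k <= n)
  dist <- 1 - tanimotoMatrix(fp)
  pop <- rowSums(fp)
  first <- if (is.null(seed)) {
    cand <- which(pop == max(pop))
    cand[order(ids[cand])][1]
  } else withSeed(seed, sample.int(n, 1))
  picked <- first
  minDist <- dist[, first]
  while (length(picked) < k) {
    minDist[picked] <- -Inf
    best <- which(minDist == max(minDist))
    nxt <- best[order(ids[best])][1]
    picked <- c(picked, nxt)
    minDist <- pmin(minDist, dist[, nxt])
  }
  picked
}

#' Per-class MaxMin diversity split
#'
#' Within each activity class independently, picks the most diverse
#' round(fraction * n_class) compounds into the training set by greedy
#' MaxMin on Tanimoto distance between Morgan fingerprints; the remainder
#' forms the validation set. Class ratios are therefore preserved to within
#' one compound per class. The first pick is the compound with the largest
#' fingerprint popcount (deterministic); set \code{randomStart = TRUE} to
#' seed-randomize it.
#'
#' @param fingerprints logical matrix from \code{\link{morganFingerprint}}.
#' @param ids compound identifiers (canonical SMILES), one per row.
#' @param labels ACT/INA class labels, one per row.
#' @param fraction training fraction (default 0.8).
#' @param seed used only when \code{randomStart = TRUE}.
#' @param randomStart randomize the initial pick per class.
#' @return a \linkS4class{DatasetSplit}.
#' @export
maxMinSplit <- function(fingerprints, ids, labels, fraction = 0.8,
                        seed = 1, randomStart = FALSE) {
  stopifnot(nrow(fingerprints) == length(ids), length(ids) == length(labels))
  labels <- asClassFactor(labels)
  trainIds <- character(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (!length(idx)) next
    if (length(idx) < 2) stop("class ", lv, " has fewer than 2 compounds")
    k <- floor(fraction * length(idx) + 0.5)
    k <- min(max(k, 1L), length(idx) - 1L)
    pick <- maxMinPick(fingerprints[idx, , drop = FALSE], ids[idx], k,
                       seed = if (randomStart) deriveSeed(seed, lv) else NULL)
    trainIds <- c(trainIds, ids[idx][pick])
  }
  new("DatasetSplit", trainIds = trainIds,
      validIds = setdiff(ids, trainIds), fraction = fraction, perClass = TRUE)
}

#' PCA coverage check of a data split
#'
#' Fits a PCA on the pooled descriptor block of all supplied sets and
#' reports the cumulative variance captured by the first two components plus
#' each set's score bounding box, to verify that training, validation and
#' any external set occupy the same region of property space.
#'
#' @param ... named numeric matrices sharing columns (e.g. train =, valid =).
#' @return list(variance_explained_pc1_2, ranges = per-set score ranges).
#' @export
pcaCoverage <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  cols <- Reduce(intersect, lapply(sets, colnames))
  if (length(cols) < 2) stop("need at least 2 shared descriptors")
  pooled <- do.call(rbind, lapply(sets, function(s) s[, cols, drop = FALSE]))
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
  ve <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  grp <- rep(names(sets), vapply(sets, nrow, 1L))
  ranges <- lapply(split(as.data.frame(scores), grp), function(s)
    list(pc1 = range(s$PC1), pc2 = range(s$PC2)))
  list(variance_explained_pc1_2 = ve, ranges = ranges[names(sets)])
}

#' Write a split manifest CSV
#'
#' @param split a \linkS4class{DatasetSplit}.
#' @param path output path; columns compound_id, subset (TS/VS).
#' @export
writeSplitManifest <- function(split, path) {
  stopifnot(is(split, "DatasetSplit"))
  df <- rbind(data.frame(compound_id = split@trainIds, subset = "TS"),
              data.frame(compound_id = split@validIds, subset = "VS"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
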