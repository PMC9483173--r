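# Open 2D descriptor backend plus the pruning / normalization stages.
# The pipeline is descriptor-agnostic: precomputed descriptor CSVs (e.g.
# from commercial packages) can be supplied instead of the built-in backend.

graphDescriptors <- function(mol) {
  els <- mol$elements
  nA <- length(els)
  bonds <- mol$bonds
  nB <- nrow(bonds)
  deg <- tabulate(c(bonds$from, bonds$to), nbins = nA)
  halos <- c("F", "Cl", "Br", "I")
  ring <- ringAtoms(mol)
  out <- c(
    nAtoms = nA, nBonds = nB, nRings = max(0L, nB - nA + 1L),
    nC = sum(els == "C"), nN = sum(els == "N"), nO = sum(els == "O"),
    nS = sum(els == "S"), nHal = sum(els %in% halos),
    nCl = sum(els == "Cl"),
    fracHetero = mean(els != "C"),
    nRingAtoms = sum(ring), fracRing = mean(ring),
    degMax = if (nA) max(deg) else 0,
    zagreb1 = sum(deg^2))
  if (nB) {
    di <- deg[bonds$from]; dj <- deg[bonds$to]
    out <- c(out,
             zagreb2 = sum(di * dj),
             randic = sum(1 / sqrt(di * dj)))
  } else out <- c(out, zagreb2 = 0, randic = 0)
  # distance-based indices on the heavy-atom graph
  if (nA >= 2 && nB >= 1) {
    D <- igraph::distances(molGraph(mol))
    fin <- is.finite(D) & D > 0
    wiener <- sum(D[fin]) / 2
    harary <- sum(1 / D[fin]) / 2
    ecc <- apply(ifelse(is.finite(D), D, 0), 1, max)
    s <- rowSums(ifelse(is.finite(D), D, 0))
    mu <- nB - nA + 1L
    eij <- 1 / sqrt(s[bonds$from] * s[bonds$to])
    balaban <- if (all(s[c(bonds$from, bonds$to)] > 0))
      nB / (mu + 1) * sum(eij) else 0
    out <- c(out, wiener = wiener, harary = harary,
             diameter = max(ecc), meanEcc = mean(ecc),
             eccConn = sum(deg * ecc), balabanJ = balaban)
  } else {
    out <- c(out, wiener = 0, harary = 0, diameter = 0, meanEcc = 0,
             eccConn = 0, balabanJ = 0)
  }
  out
}

#' Compute 2D molecular descriptors
#'
#' The built-in \code{"obgraph2d"} backend combines OpenBabel physicochemical
#' properties (MW, logP, TPSA, molar refractivity, H-bond donor/acceptor
#' counts) with element counts and topological indices (Wiener, Harary,
#' Zagreb, Randic, Balaban J, eccentricity-based) computed on the heavy-atom
#' graph. All descriptors are conformer-independent.
#'
#' @param smiles character vector of standardized canonical SMILES.
#' @param backend descriptor backend id (only \code{"obgraph2d"} is built in).
#' @return a \linkS4class{DescriptorMatrix}; compounds whose descriptor
#'   computation fails are dropped with a warning.
#' @export
computeDescriptors <- function(smiles, backend = "obgraph2d") {
  if (backend != "obgraph2d")
    stop("unknown descriptor backend: ", backend)
  stopifnot(length(smiles) >= 1)
  mols <- parseMolecules(smiles)
  ok <- !vapply(mols, is.null, TRUE)
  if (any(!ok))
    warning(sum(!ok), " compounds dropped: descriptor computation failed")
  if (!any(ok)) stop("descriptor computation failed for every compound")
  smiles <- smiles[ok]; mols <- mols[ok]
  gd <- t(vapply(mols, graphDescriptors, graphDescriptors(mols[[1]])))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    setNames(smiles, paste0("m", seq_along(smiles)))))
  pb <- ChemmineR::propOB(sdf)
  num <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  pm <- as.matrix(pb[, intersect(num, names(pb)), drop = FALSE])
  storage.mode(pm) <- "double"
  vals <- cbind(pm, gd)
  rownames(vals) <- smiles
  new("DescriptorMatrix", values = vals, normStats = data.frame(),
      backend = backend)
}

#' Prune uninformative and redundant descriptors
#'
#' Removes, in order: (1) descriptors with any missing value; (2)
#' near-constant descriptors (sd < 0.01); (3) one member of every pair with
#' absolute Pearson correlation > 0.95. For correlated pairs the survivor is
#' decided by a fixed name-sorted order (the later name is dropped) so the
#' result is deterministic.
#'
#' @param m a \linkS4class{DescriptorMatrix} (raw, possibly with NAs).
#' @param sdMin near-constant cutoff (default 0.01).
#' @param corMax absolute pair-correlation cutoff (default 0.95).
#' @return list(matrix = pruned \linkS4class{DescriptorMatrix},
#'   removed = data.frame(name, reason)).
#' @export
pruneDescriptors <- function(m, sdMin = 0.01, corMax = 0.95) {
  stopifnot(is(m, "DescriptorMatrix"))
  v <- m@values
  removed <- data.frame(name = character(0), reason = character(0))
  hasNA <- colnames(v)[colSums(is.na(v)) > 0]
  if (length(hasNA)) {
    removed <- rbind(removed, data.frame(name = hasNA, reason = "missing"))
    v <- v[, setdiff(colnames(v), hasNA), drop = FALSE]
  }
  sds <- apply(v, 2, sd)
  flat <- colnames(v)[sds < sdMin]
  if (length(flat)) {
    removed <- rbind(removed, data.frame(name = flat, reason = "near-constant"))
    v <- v[, setdiff(colnames(v), flat), drop = FALSE]
  }
  if (ncol(v) >= 2) {
    ord <- order(colnames(v))
    v <- v[, ord, drop = FALSE]
    cm <- abs(cor(v))
    dropIdx <- logical(ncol(v))
    for (j in seq_len(ncol(v))) {
      if (dropIdx[j]) next
      later <- which(cm[j, ] > corMax)
      later <- later[later > j & !dropIdx[later]]
      dropIdx[later] <- TRUE
    }
    if (any(dropIdx)) {
      removed <- rbind(removed, data.frame(name = colnames(v)[dropIdx],
                                           reason = "correlated"))
      v <- v[, !dropIdx, drop = FALSE]
    }
  }
  if (!ncol(v)) stop("all descriptors removed by pruning")
  list(matrix = new("DescriptorMatrix", values = v,
                    normStats = data.frame(), backend = m@backend),
       removed = removed)
}

#' Z-score normalization of a descriptor matrix
#'
#' In fit mode (no \code{stats}), each column is centered and scaled to unit
#' standard deviation and the statistics are stored in the result. In apply
#' mode the supplied training statistics are used verbatim, as required for
#' validation and external sets.
#'
#' @param m a \linkS4class{DescriptorMatrix}.
#' @param stats optional data.frame(name, mean, sd) from a fitted matrix.
#' @return normalized \linkS4class{DescriptorMatrix} with \code{normStats}.
#' @export
normalizeDescriptors <- function(m, stats = NULL) {
  stopifnot(is(m, "DescriptorMatrix"))
  v <- m@values
  if (is.null(stats)) {
    mu <- colMeans(v)
    sdv <- apply(v, 2, sd)
    if (any(sdv == 0))
      stop("zero-sd descriptor in fit mode; prune first: ",
           paste(colnames(v)[sdv == 0], collapse = ", "))
    stats <- data.frame(name = colnames(v), mean = unname(mu), sd = unname(sdv))
  } else {
    missing <- setdiff(colnames(v), stats$name)
    if (length(missing))
      stop("no normalization stats for: ", paste(missing, collapse = ", "))
    stats <- stats[match(colnames(v), stats$name), , drop = FALSE]
  }
  vz <- sweep(sweep(v, 2, stats$mean, "-"), 2, stats$sd, "/")
  new("DescriptorMatrix", values = vz, normStats = stats, backend = m@backend)
}

#' Read / write descriptor CSVs
#'
#' Round-trip format: first column \code{compound_id} (canonical SMILES),
#' remaining columns named descriptors.
#'
#' @param m a \linkS4class{DescriptorMatrix}; \code{path} a CSV path.
#' @param path CSV path.
#' @param backend backend label recorded when reading precomputed files.
#' @export
writeDescriptorMatrix <- function(m, path) {
  stopifnot(is(m, "DescriptorMatrix"))
  df <- data.frame(compound_id = rownames(m@values), m@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDescriptorMatrix
#' @export
readDescriptorMatrix <- function(path, backend = "precomputed") {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "compound_id")
    stop("descriptor CSV must start with a compound_id column")
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$compound_id
  new("DescriptorMatrix", values = v, normStats = data.frame(),
      backend = backend)
}
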