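# Desk-scale synthetic fixtures with the statistical structure the pipeline
# assumes: an unbalanced binary label over a small set of class-informative
# descriptors among many noise descriptors, and raw activity tables with
# replicate spread, unit mixtures, outliers and filter-violating records.

#' Generate a labeled descriptor dataset
#'
#' Draws class labels to match \code{classRatio} exactly (INA:ACT), then
#' informative descriptors from Normal(+/- effectSize/2 by class, 1) and
#' noise descriptors from Normal(0, 1). Deterministic given the seed.
#'
#' @param n total compounds; must be divisible by sum(classRatio).
#' @param classRatio integer pair c(INA, ACT), e.g. c(5, 1) or c(1, 1).
#' @param nInformative,nNoise descriptor counts (sum >= 2).
#' @param effectSize standardized between-class mean shift of informative
#'   descriptors (default 1.5).
#' @param seed random seed.
#' @return list(X = matrix, y = factor INA/ACT, planted = informative names).
#' @export
generateDescriptorDataset <- function(n = 600, classRatio = c(5, 1),
                                      nInformative = 10, nNoise = 50,
                                      effectSize = 1.5, seed = 1) {
  stopifnot(nInformative + nNoise >= 2, effectSize >= 0, all(classRatio > 0))
  s <- sum(classRatio)
  if (n %% s != 0)
    stop("n = ", n, " cannot realize the ", classRatio[1], ":",
         classRatio[2], " class ratio exactly")
  nIna <- n / s * classRatio[1]
  nAct <- n / s * classRatio[2]
  y <- factor(c(rep("INA", nIna), rep("ACT", nAct)), levels = .classLevels)
  shift <- ifelse(y == "ACT", effectSize / 2, -effectSize / 2)
  withSeed(seed, {
    Xi <- if (nInformative)
      matrix(rnorm(n * nInformative, mean = rep(shift, nInformative)),
             n, nInformative) else NULL
    Xn <- if (nNoise) matrix(rnorm(n * nNoise), n, nNoise) else NULL
    X <- cbind(Xi, Xn)
  })
  planted <- if (nInformative)
    sprintf("inf_%02d", seq_len(nInformative)) else character(0)
  colnames(X) <- c(planted,
                   if (nNoise) sprintf("noise_%02d", seq_len(nNoise)))
  rownames(X) <- sprintf("cmpd_%04d", seq_len(n))
  list(X = X, y = y, planted = planted)
}

# enumerated drug-like SMILES: scaffold x linker x tail substitutions,
# canonicalized and deduplicated (deterministic order)
buildSmilesLibrary <- function(nMax = 800) {
  scaffolds <- c("c1ccc(%s)cc1", "c1ccnc(%s)c1", "c1cc(%s)sc1",
                 "c1cc(%s)oc1", "C1CCC(%s)CC1", "C1CCC(%s)NC1",
                 "C1CC(%s)OC1", "c1ccc(%s)cc1F", "c1ccc(%s)cc1Cl",
                 "c1ccc(%s)cc1OC", "c1ccc(%s)cc1C", "c1ccc(%s)cc1N")
  linkers <- c("", "C", "CC", "CCC", "C(=O)", "CC(=O)")
  tails <- c("C", "N", "O", "Cl", "F", "C(=O)O", "N(C)C", "OC")
  groups <- as.vector(outer(linkers, tails, paste0))
  raw <- as.vector(vapply(scaffolds, function(sc)
    sprintf(sc, groups), character(length(groups))))
  pairs <- expand.grid(g1 = groups[seq_len(12)], g2 = groups[seq_len(12)],
                       stringsAsFactors = FALSE)
  raw <- c(raw, sprintf("c1cc(%s)ccc1%s", pairs$g1, pairs$g2))
  can <- obCanonical(raw, neutralize = TRUE)
  can <- can[!is.na(can)]
  can <- can[!duplicated(can)]
  head(can, nMax)
}

#' Generate a raw ChEMBL-style activity table
#'
#' Emits replicate IC50 records (mixed units) for valid small-molecule
#' SMILES drawn from an internal enumerated library, with controllable
#' within-compound spread, a configurable fraction of replicate-outlier
#' compounds (spread engineered above the sigma = 2 exclusion cutoff), a few
#' comment-only "Not Active" compounds, and one record deliberately
#' violating each curation filter (wrong organism, functional assay, non-IC50
#' type, data-validity warning, an iron salt, an unparseable string).
#'
#' @param nCompounds compounds with numeric activity.
#' @param meanPIC50,sdPIC50 between-compound activity location and residual
#'   spread.
#' @param structureEffect strength (pIC50 units per SD) of the latent
#'   structure-activity signal, a standardized blend of lipophilicity and
#'   size (0.7 z(logP) + 0.3 z(MW)) so that descriptor-based models can
#'   genuinely recover activity; 0 gives structure-independent labels.
#' @param withinSd replicate spread for normal compounds.
#' @param fractionOutliers expected fraction of sigma > 2 compounds.
#' @param replicateLambda replicate count is 1 + Poisson(lambda).
#' @param nCommentInactive comment-only inactive compounds to add.
#' @param injectViolations add the six filter-violating records.
#' @param seed random seed.
#' @return list(records = activity data.frame (internal field names),
#'   truth = data.frame(smiles, pIC50_true, outlier)).
#' @export
generateActivityTable <- function(nCompounds = 200, meanPIC50 = 5.5,
                                  sdPIC50 = 0.8, structureEffect = 1.2,
                                  withinSd = 0.3,
                                  fractionOutliers = 0.05,
                                  replicateLambda = 1,
                                  nCommentInactive = 5,
                                  injectViolations = TRUE, seed = 1) {
  lib <- buildSmilesLibrary()
  if (nCompounds + nCommentInactive > length(lib))
    stop("library has only ", length(lib), " distinct structures")
  base <- list(standard_type = "IC50", standard_units = "M",
               target_organism = "Homo sapiens", assay_type = "B",
               data_validity_comment = "", activity_comment = "")
  mkrec <- function(smiles, value, units, over = list()) {
    f <- modifyList(base, over)
    data.frame(smiles = smiles, standard_type = f$standard_type,
               standard_value = value, standard_units = units,
               target_organism = f$target_organism,
               assay_type = f$assay_type,
               data_validity_comment = f$data_validity_comment,
               activity_comment = f$activity_comment)
  }
  unitPick <- c("M", "mM", "uM", "nM")
  unitScale <- c(M = 1, mM = 1e3, uM = 1e6, nM = 1e9)
  recs <- list(); truth <- list()
  withSeed(seed, {
    sm <- sample(lib, nCompounds + nCommentInactive)
    numeric_sm <- sm[seq_len(nCompounds)]
    comment_sm <- sm[nCompounds + seq_len(nCommentInactive)]
    signal <- rep(0, nCompounds)
    if (structureEffect > 0) {
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(
        setNames(numeric_sm, paste0("m", seq_len(nCompounds)))))
      pp <- ChemmineR::propOB(sdf)
      z <- function(x) (x - mean(x)) / max(sd(x), 1e-9)
      signal <- structureEffect * (0.7 * z(pp$logP) + 0.3 * z(pp$MW))
    }
    for (i in seq_len(nCompounds)) {
      p0 <- meanPIC50 + signal[i] + rnorm(1, 0, sdPIC50)
      out <- runif(1) < fractionOutliers
      m <- 1 + rpois(1, replicateLambda)
      if (out) m <- max(m, 2)
      ps <- rnorm(m, p0, withinSd)
      if (out) ps[1:2] <- p0 + c(-3.2, 3.2) + rnorm(2, 0, 0.1)
      for (p in ps) {
        u <- sample(unitPick, 1)
        recs[[length(recs) + 1]] <-
          mkrec(numeric_sm[i], 10^(-p) * unitScale[[u]], u)
      }
      truth[[i]] <- data.frame(smiles = numeric_sm[i], pIC50_true = p0,
                               outlier = out)
    }
    for (s in comment_sm)
      recs[[length(recs) + 1]] <-
        mkrec(s, NA_real_, "", over = list(activity_comment = "Not Active"))
  })
  if (injectViolations) {
    v <- lib[1]
    recs <- c(recs, list(
      mkrec(v, 1e-6, "M", list(target_organism = "Rattus norvegicus")),
      mkrec(v, 1e-6, "M", list(assay_type = "F")),
      mkrec(v, 1e-6, "M", list(standard_type = "Ki")),
      mkrec(v, 1e-6, "M", list(data_validity_comment = "Potential transcription error")),
      mkrec("[Fe+2].[O-]S([O-])(=O)=O", 1e-6, "M"),
      mkrec("][not_a_smiles", 1e-6, "M")))
  }
  list(records = do.call(rbind, recs),
       truth = do.call(rbind, truth))
}

#' Write an activity table with ChEMBL-style column names
#'
#' @param records data.frame from \code{\link{generateActivityTable}}.
#' @param path output CSV path.
#' @export
writeActivityTable <- function(records, path) {
  out <- records
  names(out) <- unname(.defaultColumnMap[names(records)])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
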