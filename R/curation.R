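# Curation of raw ChEMBL-style activity exports into a labeled, QSAR-ready
# compound set: entry filters, structure standardization, pIC50 conversion,
# replicate aggregation with the sigma > 2 outlier rule, and dual-threshold
# class labels.

.defaultColumnMap <- c(
  smiles = "canonical_smiles", standard_type = "standard_type",
  standard_value = "standard_value", standard_units = "standard_units",
  target_organism = "target_organism", assay_type = "assay_type",
  data_validity_comment = "data_validity_comment",
  activity_comment = "activity_comment")

#' Read a raw activity export
#'
#' Reads a ChEMBL-style TSV/CSV activity table and renames columns to the
#' internal field names via a configurable mapping.
#'
#' @param path file path.
#' @param columnMap named character vector mapping internal field names
#'   (names) to file column names (values); defaults to ChEMBL field names.
#' @param sep field separator; guessed from the extension when NULL.
#' @return data.frame of activity records.
#' @export
readActivityTable <- function(path, columnMap = NULL, sep = NULL) {
  cm <- .defaultColumnMap
  if (!is.null(columnMap)) cm[names(columnMap)] <- columnMap
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cm, names(df))
  if (length(missing))
    stop("activity table lacks columns: ", paste(missing, collapse = ", "))
  out <- df[, cm]
  names(out) <- names(cm)
  out$standard_value <- suppressWarnings(as.numeric(out$standard_value))
  out
}

#' Filter raw activity entries
#'
#' Retains records that are IC50 measurements on the human target from
#' direct-binding assays with no data-validity warning. Comment-only
#' "not active" records (no numeric value) are retained so that compounds
#' measured only qualitatively can be labeled inactive downstream.
#'
#' @param records data.frame of activity records (see
#'   \code{\link{readActivityTable}}).
#' @return list with \code{kept} (subset of \code{records}, order preserved)
#'   and \code{rejected} (data.frame with a \code{reason} column naming the
#'   first failing rule).
#' @export
filterActivityEntries <- function(records) {
  need <- names(.defaultColumnMap)
  if (!all(need %in% names(records)))
    stop("records lack fields: ", paste(setdiff(need, names(records)), collapse = ", "))
  n <- nrow(records)
  if (!n) stop("empty activity table")
  reason <- rep(NA_character_, n)
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  commentInactive <- !blank(records$activity_comment) &
    grepl("not\\s*active|inactive", records$activity_comment, ignore.case = TRUE) &
    is.na(records$standard_value)
  badRow <- blank(records$smiles)
  reason[is.na(reason) & badRow] <- "unparseable_row"
  typeOk <- toupper(trimws(records$standard_type)) == "IC50" | commentInactive
  reason[is.na(reason) & !typeOk] <- "standard_type"
  orgOk <- trimws(records$target_organism) == "Homo sapiens"
  reason[is.na(reason) & !orgOk] <- "target_organism"
  assayOk <- trimws(records$assay_type) == "B"
  reason[is.na(reason) & !assayOk] <- "assay_type"
  validOk <- blank(records$data_validity_comment)
  reason[is.na(reason) & !validOk] <- "data_validity_comment"
  keep <- is.na(reason)
  if (sum(badRow))
    warning(sum(badRow), " unparseable rows skipped")
  if (!any(keep)) stop("all activity records rejected by the entry filters")
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Standardize structures to QSAR-ready canonical SMILES
#'
#' Strips stereochemistry, removes salt/counterion fragments (keeping the
#' largest organic fragment), neutralizes charges where chemically valid, and
#' canonicalizes through OpenBabel. Organometallics, inorganics, compounds
#' with elements outside the allowed organic set (H, B, C, N, O, F, Si, P, S,
#' Cl, Se, Br, I), true multi-component mixtures (two fragments each with
#' more than 6 heavy atoms) and unparseable strings are rejected.
#'
#' @param smiles character vector of input SMILES.
#' @return data.frame with columns \code{input_smiles},
#'   \code{canonical_smiles} (NA when rejected), \code{status}
#'   (\code{"OK"}/\code{"REJECTED"}) and \code{reason}.
#' @examples
#' \dontrun{standardizeStructures(c("C[C@@H](N)C(=O)O.Cl", "CCO"))}
#' @export
standardizeStructures <- function(smiles) {
  n <- length(smiles)
  reason <- rep(NA_character_, n)
  fragKept <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(trimws(s))) { reason[i] <- "unparseable"; next }
    s <- stripStereo(trimws(s))
    # crude syntax gate: SMILES alphabet and balanced brackets/parentheses
    if (!smilesAlphabetOk(s) || !smilesBalanced(s)) {
      reason[i] <- "unparseable"; next
    }
    frags <- splitFragments(s)
    ha <- vapply(frags, heavyAtomCount, 1L)
    organic <- vapply(frags, function(f) "C" %in% smilesElements(f), TRUE)
    if (!any(organic)) { reason[i] <- "inorganic"; next }
    if (sum(organic & ha > 6) >= 2) { reason[i] <- "mixture"; next }
    cand <- frags[organic]
    candHa <- ha[organic]
    best <- cand[order(-candHa, cand)][1]
    els <- unique(smilesElements(best))
    if (length(setdiff(els, .allowedElements))) { reason[i] <- "element"; next }
    fragKept[i] <- best
  }
  todo <- which(is.na(reason))
  canonical <- rep(NA_character_, n)
  if (length(todo)) {
    can <- obCanonical(fragKept[todo], neutralize = TRUE)
    canonical[todo] <- can
    reason[todo][is.na(can)] <- "unparseable"
  }
  data.frame(input_smiles = smiles, canonical_smiles = canonical,
             status = ifelse(is.na(reason), "OK", "REJECTED"),
             reason = ifelse(is.na(reason), "", reason),
             stringsAsFactors = FALSE)
}

#' Convert IC50 to pIC50
#'
#' pIC50 = -log10(IC50 in molar). Supported units: M, mM, uM (µM), nM.
#'
#' @param ic50 numeric IC50 values (> 0).
#' @param units character vector of units, recycled.
#' @return numeric pIC50; NA (with a warning) for non-positive values or
#'   unknown units.
#' @examples toPIC50(1e-6, "M")  # 6
#' @export
toPIC50 <- function(ic50, units) {
  units <- rep_len(units, length(ic50))
  mult <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  key <- trimws(units)
  key[key %in% c("µM", "μM", "um", "UM")] <- "uM"
  key[key == "nm"] <- "nM"
  molar <- ic50 * unname(mult[key])
  bad <- is.na(molar) | molar <= 0
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " IC50 values dropped (non-positive or unknown units)")
  out <- rep(NA_real_, length(ic50))
  out[!bad] <- -log10(molar[!bad])
  out
}

#' Aggregate replicate pIC50 measurements
#'
#' Replicates of one canonical structure are averaged; the sample standard
#' deviation (n - 1 denominator, 0 for a single replicate) measures the
#' replicate spread, and compounds with sigma > 2 are flagged as outliers to
#' be excluded.
#'
#' @param values numeric pIC50 replicates for one compound (length >= 1).
#' @return list(mean, sigma, kept) with \code{kept = sigma <= 2}.
#' @examples aggregateDuplicates(c(6.0, 6.2, 6.4))
#' @export
aggregateDuplicates <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no pIC50 values to aggregate")
  sigma <- if (length(values) == 1L) 0 else sd(values)
  list(mean = mean(values), sigma = sigma, kept = sigma <= 2)
}

#' Assign the activity class at a potency threshold
#'
#' A compound is an hERG blocker (ACT) when pIC50 >= threshold; the threshold
#' 6 corresponds to IC50 <= 1 uM and 5 to IC50 <= 10 uM. Compounds without a
#' numeric pIC50 that were curated from "not active" comments are INA at both
#' thresholds.
#'
#' @param pic50 numeric pIC50 (NA for comment-only inactives).
#' @param threshold 5 or 6.
#' @return character vector of "ACT"/"INA".
#' @export
assignLabel <- function(pic50, threshold) {
  stopifnot(threshold %in% c(5, 6))
  ifelse(is.na(pic50), "INA", ifelse(pic50 >= threshold, "ACT", "INA"))
}

#' Curate a raw activity table end to end
#'
#' Applies the entry filters, standardizes structures, converts IC50 values
#' to pIC50, aggregates replicates per canonical SMILES (dropping sigma > 2
#' outliers), and assigns class labels at both potency thresholds. Compounds
#' with only qualitative "not active" annotations are kept label-only; when
#' a compound has both numeric records and such a comment, the numeric values
#' win.
#'
#' @param records data.frame of raw activity records.
#' @return a \linkS4class{CuratedSet}.
#' @export
curateActivityData <- function(records) {
  flt <- filterActivityEntries(records)
  kept <- flt$kept
  rej <- flt$rejected[, c("smiles", "reason"), drop = FALSE]
  std <- standardizeStructures(kept$smiles)
  bad <- std$status == "REJECTED"
  if (any(bad))
    rej <- rbind(rej, data.frame(smiles = kept$smiles[bad],
                                 reason = std$reason[bad]))
  kept <- kept[!bad, , drop = FALSE]
  kept$canonical_smiles <- std$canonical_smiles[!bad]
  if (!nrow(kept)) stop("no records survived standardization")

  isComment <- is.na(kept$standard_value)
  kept$pIC50 <- NA_real_
  if (any(!isComment)) {
    suppressWarnings(
      kept$pIC50[!isComment] <- toPIC50(kept$standard_value[!isComment],
                                        kept$standard_units[!isComment]))
    drop <- !isComment & is.na(kept$pIC50)
    if (any(drop)) {
      rej <- rbind(rej, data.frame(smiles = kept$smiles[drop],
                                   reason = "bad_value_or_units"))
      kept <- kept[!drop, , drop = FALSE]
      isComment <- is.na(kept$standard_value)
    }
  }

  out <- lapply(split(kept, kept$canonical_smiles), function(grp) {
    vals <- grp$pIC50[!is.na(grp$pIC50)]
    if (length(vals)) {                       # numeric records win
      agg <- aggregateDuplicates(vals)
      data.frame(canonical_smiles = grp$canonical_smiles[1],
                 pIC50 = agg$mean, sigma = agg$sigma,
                 n_records = length(vals), kept = agg$kept)
    } else {
      data.frame(canonical_smiles = grp$canonical_smiles[1],
                 pIC50 = NA_real_, sigma = 0,
                 n_records = nrow(grp), kept = TRUE)
    }
  })
  cp <- do.call(rbind, out)
  rownames(cp) <- NULL
  outl <- !cp$kept
  if (any(outl))
    rej <- rbind(rej, data.frame(smiles = cp$canonical_smiles[outl],
                                 reason = "sigma_outlier"))
  cp <- cp[cp$kept, setdiff(names(cp), "kept"), drop = FALSE]
  cp$label_t6 <- assignLabel(cp$pIC50, 6)
  cp$label_t5 <- assignLabel(cp$pIC50, 5)
  rownames(rej) <- NULL
  new("CuratedSet", compounds = cp, rejections = rej)
}

#' Write / read a curated dataset as CSV
#'
#' @param x a \linkS4class{CuratedSet}.
#' @param path output CSV path; for the reader, the input path.
#' @return \code{readCuratedSet} returns a \linkS4class{CuratedSet} (with an
#'   empty rejection log).
#' @export
writeCuratedSet <- function(x, path) {
  stopifnot(is(x, "CuratedSet"))
  write.csv(x@compounds, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCuratedSet
#' @export
readCuratedSet <- function(path) {
  cp <- read.csv(path, stringsAsFactors = FALSE)
  new("CuratedSet", compounds = cp,
      rejections = data.frame(smiles = character(0), reason = character(0)))
}
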