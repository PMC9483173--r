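# SMILES handling built on the OpenBabel stack (ChemmineR/ChemmineOB).
# Element bookkeeping is done on the SMILES text itself so that rejection
# rules (inorganic, organometallic, unusual element, mixture) fire before
# any toolkit call.

.allowedElements <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                      "Cl", "Se", "Br", "I")

# element symbols appearing in one SMILES fragment (H excluded from counts)
smilesElements <- function(smiles) {
  els <- character(0)
  # bracket atoms: isotope? element charge? etc.
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  rest <- gsub("\\[[^]]*\\]", "", smiles)
  for (b in brackets) {
    m <- regmatches(b, regexec("\\[[0-9]*([A-Za-z][a-z]?)", b))[[1]]
    if (length(m) == 2) {
      sym <- m[2]
      # two-char matches like "Cr" are real elements; lone aromatic organics
      # (c, n, o, s, p, b) and aromatic se/as need capitalization
      sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      # [nH] captures "nH": the H is hydrogen count, not part of the symbol
      if (nchar(sym) == 2 && substring(sym, 2) == "H" &&
          substr(sym, 1, 1) %in% c("C", "N", "O", "S", "P", "B"))
        sym <- substr(sym, 1, 1)
      els <- c(els, sym)
    }
  }
  # organic subset outside brackets: two-char halogens first
  for (two in c("Cl", "Br")) {
    n <- lengths(regmatches(rest, gregexpr(two, rest, fixed = TRUE)))
    els <- c(els, rep(two, n))
    rest <- gsub(two, "", rest, fixed = TRUE)
  }
  singles <- regmatches(rest, gregexpr("[BCNOPSFIbcnops]", rest))[[1]]
  els <- c(els, toupper(singles))
  els
}

heavyAtomCount <- function(smiles) sum(smilesElements(smiles) != "H")

# character-level syntax gate: SMILES alphabet only
.smilesChars <- c(letters, LETTERS, 0:9, "@", "+", "-", "[", "]", "(", ")",
                  "=", "#", "$", "%", ":", "*", ".", "/", "\\")

smilesAlphabetOk <- function(s)
  all(strsplit(s, "")[[1]] %in% .smilesChars)

# balanced (), [] with correct nesting order
smilesBalanced <- function(s) {
  depthP <- 0; depthB <- 0
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depthP <- depthP + 1
    else if (ch == ")") { depthP <- depthP - 1; if (depthP < 0) return(FALSE) }
    else if (ch == "[") { depthB <- depthB + 1; if (depthB > 1) return(FALSE) }
    else if (ch == "]") { depthB <- depthB - 1; if (depthB < 0) return(FALSE) }
  }
  depthP == 0 && depthB == 0
}

stripStereo <- function(smiles) gsub("[@/\\\\]", "", smiles)

splitFragments <- function(smiles) strsplit(smiles, ".", fixed = TRUE)[[1]]

# batch neutralize + canonicalize through OpenBabel; NA for unparseable input
obCanonical <- function(smiles, neutralize = TRUE) {
  if (!length(smiles)) return(character(0))
  tags <- paste0("m", seq_along(smiles))
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, tags, sep = "\t"), fin)
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(0), args = character(0))
  ok <- tryCatch({
    ChemmineOB::convertFormatFile("SMI", "CAN", fin, fout, options = opts)
    TRUE
  }, error = function(e) FALSE)
  out <- rep(NA_character_, length(smiles))
  if (ok && file.exists(fout)) {
    lines <- readLines(fout, warn = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2 && nzchar(p[1])) {
        i <- match(trimws(p[2]), tags)
        if (!is.na(i)) out[i] <- p[1]
      }
    }
  }
  out
}

# connection tables for standardized SMILES: list of
# list(elements = chr, bonds = data.frame(from, to, order))
parseMolecules <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  nm <- paste0("m", seq_along(smiles))
  toSdf <- function(s, n) tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(s, n))),
    error = function(e) NULL)
  sdf <- toSdf(smiles, nm)
  if (is.null(sdf)) {
    # batch conversion failed: isolate the convertible molecules
    pieces <- lapply(seq_along(smiles), function(i) toSdf(smiles[i], nm[i]))
    pieces <- pieces[!vapply(pieces, is.null, TRUE)]
    if (!length(pieces)) return(vector("list", length(smiles)))
    sdf <- Reduce(c, pieces)
  }
  valid <- ChemmineR::validSDF(sdf)
  out <- vector("list", length(smiles))
  sdfIds <- ChemmineR::sdfid(sdf)
  for (i in seq_along(smiles)) {
    j <- match(nm[i], sdfIds)
    if (is.na(j) || !valid[j]) next
    mol <- sdf[[j]]
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    els <- sub("_.*$", "", rownames(ab))
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
      data.frame(from = integer(0), to = integer(0), order = integer(0))
    else data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    # drop explicit hydrogens if any
    keep <- which(els != "H")
    if (length(keep) < length(els)) {
      remap <- match(seq_along(els), keep)
      bonds <- bonds[bonds$from %in% keep & bonds$to %in% keep, , drop = FALSE]
      bonds$from <- remap[bonds$from]; bonds$to <- remap[bonds$to]
      els <- els[keep]
    }
    out[[i]] <- list(elements = els, bonds = bonds)
  }
  out
}

molGraph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$elements)))
}

# ring membership: endpoints of non-bridge edges lie on a cycle
ringAtoms <- function(mol) {
  n <- length(mol$elements)
  if (!nrow(mol$bonds)) return(rep(FALSE, n))
  g <- molGraph(mol)
  br <- igraph::bridges(g)
  onRing <- rep(FALSE, n)
  nonBridge <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  if (length(nonBridge)) {
    onRing[mol$bonds$from[nonBridge]] <- TRUE
    onRing[mol$bonds$to[nonBridge]] <- TRUE
  }
  onRing
}
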