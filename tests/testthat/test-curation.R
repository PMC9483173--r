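test_that("entry filters keep exactly the conforming records", {
  base <- data.frame(
    smiles = paste0("C", 1:10, "CO"), standard_type = "IC50",
    standard_value = 1e-6, standard_units = "M",
    target_organism = "Homo sapiens", assay_type = "B",
    data_validity_comment = "", activity_comment = "",
    stringsAsFactors = FALSE)
  base$smiles <- rep("CCO", 10)
  base$standard_type[2] <- "Ki"
  base$target_organism[5] <- "Rattus norvegicus"
  base$assay_type[8] <- "F"
  res <- filterActivityEntries(base)
  expect_equal(nrow(res$kept), 7)
  expect_equal(sort(res$rejected$reason),
               sort(c("standard_type", "target_organism", "assay_type")))
  # subset property: kept rows are a subsequence of the input
  expect_true(all(rownames(res$kept) %in% rownames(base)))
  expect_equal(res$kept, base[as.integer(rownames(res$kept)), ])
})

test_that("comment-only inactives survive the type filter, all-rejected errors", {
  rec <- data.frame(
    smiles = c("CCO", "CCN"), standard_type = c("IC50", ""),
    standard_value = c(1e-6, NA), standard_units = c("M", ""),
    target_organism = "Homo sapiens", assay_type = "B",
    data_validity_comment = "", activity_comment = c("", "Not Active"),
    stringsAsFactors = FALSE)
  res <- filterActivityEntries(rec)
  expect_equal(nrow(res$kept), 2)
  bad <- rec; bad$assay_type <- "F"
  expect_error(filterActivityEntries(bad), "all activity records rejected")
})

test_that("structure standardization strips salts and stereo, rejects junk", {
  res <- standardizeStructures(c(
    "C[C@H](N)C(=O)O.Cl",            # alanine hydrochloride
    "CC(N)C(=O)O",                   # same molecule, flat
    "CCO",
    "[Fe+2].[O-]S([O-])(=O)=O",      # iron salt: inorganic
    "CC[Pb](CC)(CC)CC",              # organolead: disallowed element
    "not_a_smiles",
    "CCCCCCCCCC.NCCCCCCCCCC"))       # two large organic fragments
  expect_equal(res$status,
               c("OK", "OK", "OK", "REJECTED", "REJECTED", "REJECTED",
                 "REJECTED"))
  expect_equal(res$reason[4:7],
               c("inorganic", "element", "unparseable", "mixture"))
  # salt stripped + stereochemistry removed: both alanine forms identical
  expect_identical(res$canonical_smiles[1], res$canonical_smiles[2])
  expect_false(grepl("Cl|@", res$canonical_smiles[1]))
})

test_that("standardization is idempotent and canonicalizing", {
  first <- standardizeStructures(testSmiles)
  expect_true(all(first$status == "OK"))
  second <- standardizeStructures(first$canonical_smiles)
  expect_identical(second$canonical_smiles, first$canonical_smiles)
  # alternative writings of the same molecules map to the same canonical form
  alt <- standardizeStructures(c("OCC", "c1ccccc1C"))
  ref <- standardizeStructures(c("CCO", "Cc1ccccc1"))
  expect_identical(alt$canonical_smiles, ref$canonical_smiles)
})

test_that("pIC50 conversion handles units and round-trips", {
  expect_equal(toPIC50(1e-6, "M"), 6)
  expect_equal(toPIC50(10, "uM"), 5)
  expect_equal(toPIC50(10^(-6.24), "M"), 6.24)
  expect_equal(toPIC50(c(1, 1000, 1e6, 1e9), c("M", "mM", "uM", "nM")),
               rep(0, 4))
  # inverse property through the molar scale
  p <- c(3.7, 5.5, 8.12)
  expect_equal(toPIC50(10^(-p), "M"), p, tolerance = 1e-9)
  expect_warning(out <- toPIC50(c(-1, 1e-6), "M"), "dropped")
  expect_true(is.na(out[1]) && !is.na(out[2]))
  # monotone decreasing in IC50
  expect_true(toPIC50(1e-9, "M") > toPIC50(1e-6, "M"))
})

test_that("replicate aggregation uses sample sd and the sigma > 2 rule", {
  a <- aggregateDuplicates(c(6.0, 6.2, 6.4))
  expect_equal(a$mean, 6.2)
  expect_equal(a$sigma, 0.2)
  expect_true(a$kept)
  expect_equal(aggregateDuplicates(7.1), list(mean = 7.1, sigma = 0, kept = TRUE))
  b <- aggregateDuplicates(c(4.0, 9.0))
  expect_equal(b$sigma, 5 / sqrt(2), tolerance = 1e-12)
  expect_false(b$kept)
})

test_that("labels follow the ACT iff pIC50 >= threshold convention", {
  expect_equal(assignLabel(6.24, 6), "ACT")   # mibefradil-like potency
  expect_equal(assignLabel(4.2, 5), "INA")
  expect_equal(assignLabel(6.0, 6), "ACT")    # boundary is ACT
  expect_equal(assignLabel(NA, 6), "INA")     # comment-only inactive
  # monotone nesting: every ACT at 6 is ACT at 5
  p <- seq(3, 9, by = 0.25)
  act6 <- assignLabel(p, 6) == "ACT"
  act5 <- assignLabel(p, 5) == "ACT"
  expect_true(all(!act6 | act5))
})

test_that("end-to-end curation deduplicates, labels and logs rejections", {
  tab <- generateActivityTable(nCompounds = 60, fractionOutliers = 0.15,
                               seed = 11)
  cs <- curateActivityData(tab$records)
  cp <- compounds(cs)
  expect_false(anyDuplicated(cp$canonical_smiles) > 0)
  expect_true(all(cp$sigma <= 2))
  expect_true(all(is.na(cp$pIC50) == (cp$label_t6 == "INA" &
                                        cp$label_t5 == "INA") |
                    !is.na(cp$pIC50)))
  rej <- rejections(cs)
  expect_true(all(c("target_organism", "assay_type", "standard_type",
                    "data_validity_comment") %in% rej$reason))
  expect_true(any(rej$reason %in% c("inorganic", "element")))
  expect_true(any(rej$reason == "unparseable"))
  # ACT at 6 nested in ACT at 5
  expect_true(all(cp$label_t5[cp$label_t6 == "ACT"] == "ACT"))
  # round trip
  f <- tempfile(fileext = ".csv")
  writeCuratedSet(cs, f)
  back <- compounds(readCuratedSet(f))
  expect_equal(back$canonical_smiles, cp$canonical_smiles)
  expect_equal(back$pIC50, cp$pIC50, tolerance = 1e-12)
})
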