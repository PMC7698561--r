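test_that("monoisotopic masses and adduct m/z reproduce the vitamin-B3 golden values", {
  # hand-summed from standard atomic masses
  expect_equal(monoisotopic_mass("C6H6N2O"), 122.0480, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C7H8N2O2"), 152.0586, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("H2O"), 18.0106, tolerance = 1e-4)

  # the published 4-decimal adduct values of the pyridone-carboxamides and
  # nicotinamide
  expect_equal(round(theoretical_mz("C7H8N2O2", "M+H[1+]"), 4), 153.0659)
  expect_equal(round(theoretical_mz("C7H8N2O2", "M-NH3+H[1+]"), 4), 136.0394)
  expect_equal(round(theoretical_mz("C6H6N2O", "M+H[1+]"), 4), 123.0553)
  expect_equal(round(theoretical_mz("C7H8N2O2", "M+Na[1+]"), 4), 175.0479)

  # doubly charged deprotonation divides by the charge
  M <- monoisotopic_mass("C10H12N4O5")
  expect_equal(theoretical_mz(M, "M-2H[2-]"), (M - 2 * 1.00727646) / 2)

  expect_error(monoisotopic_mass("C6H6X2"), "unknown element")
  expect_error(monoisotopic_mass("c6h6"), "cannot parse")
  expect_error(theoretical_mz("C6H6N2O", "M+Fe[1+]"), "unknown adduct")
})

test_that("the adduct rule set encodes exactly the six primary ions", {
  rules <- adduct_rules()
  primary <- rules$name[rules$is_primary]
  expect_setequal(primary, c("M+H[1+]", "M+Na[1+]", "M-H2O+H[1+]",
                             "M-H[1-]", "M-2H[2-]", "M-H2O-H[1-]"))
  expect_true(all(rules$polarity %in% c("positive", "negative")))
})

test_that("the packaged reference loads, is self-consistent, and covers all rules", {
  ref <- load_metabolite_reference()
  expect_gte(nrow(ref), 45)
  expect_setequal(names(reference_pathways(ref)),
                  c("vitamin_b3", "arachidonic_acid", "methionine_cysteine",
                    "purine"))
  expect_true(all(abs(ref$monoisotopic_mass -
                      monoisotopic_mass(ref$formula)) <= 1e-4))
  # every (formula, rule) pair yields a finite m/z
  rules <- adduct_rules()
  for (a in seq_len(nrow(rules))) {
    mz <- (ref$monoisotopic_mass + rules$delta[a]) / rules$charge[a]
    expect_true(all(is.finite(mz) & mz > 0))
  }
  # a corrupted stored mass is rejected
  path <- tempfile(fileext = ".tsv")
  raw <- utils::read.delim(system.file("extdata", "mini_metabolite_reference.tsv",
                                       package = "metaboselect"))
  raw$monoisotopic_mass[3] <- raw$monoisotopic_mass[3] + 0.01
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_metabolite_reference(path), "disagrees")
})

test_that("annotation hits respect mode, tolerance, and isomer multiplicity", {
  ref <- load_metabolite_reference()
  input <- data.frame(
    mz = c(153.0659, 153.0659, 123.0553, 400.123),
    rt = c(2.9, 2.9, 1.4, 8),
    p_value = c(1e-4, 1e-4, 1e-4, 0.5),
    mode = c("positive", "negative", "positive", "positive"),
    row.names = paste0("F", 1:4)
  )
  hits <- annotate_features(input, ref, tolerance_ppm = 1)
  h1 <- hits[hits$feature_id == "F1", ]
  # both pyridone-carboxamide isomers, never nicotinamide
  expect_setequal(h1$metabolite_id, c("n1_methyl_4_pyridone_5_carboxamide",
                                      "n1_methyl_2_pyridone_5_carboxamide"))
  expect_false("nicotinamide" %in% h1$metabolite_id)
  # same m/z in negative mode matches nothing (mode-gated rules)
  expect_equal(nrow(hits[hits$feature_id == "F2", ]), 0L)
  expect_true(all(abs(hits$ppm_error) <= 1))
  expect_equal(unique(hits$adduct[hits$feature_id == "F3"]), "M+H[1+]")

  # tolerance monotonicity: 1 ppm hits are a subset of 5 ppm hits
  h5 <- annotate_features(input, ref, tolerance_ppm = 5)
  key <- function(h) paste(h$feature_id, h$metabolite_id, h$adduct)
  expect_true(all(key(hits) %in% key(h5)))
  expect_error(annotate_features(input, ref[0, ], 1), "empty")
})

test_that("primary-ion enforcement keeps corroborating hits but drops K-only matches", {
  hits <- data.frame(
    feature_id = c("F1", "F2", "F3"),
    metabolite_id = c("metA", "metA", "metB"),
    adduct = c("M+H[1+]", "M+K[1+]", "M+K[1+]"),
    theoretical_mz = c(100, 138, 200),
    observed_mz = c(100, 138, 200),
    ppm_error = c(0, 0, 0),
    is_primary = c(TRUE, FALSE, FALSE),
    p_value = 0.01,
    stringsAsFactors = FALSE
  )
  out <- enforce_primary_ions(hits)
  expect_equal(out$metabolites, "metA")
  expect_equal(nrow(out$hits), 2L)   # the M+K hit of metA is kept as corroboration
  empty <- enforce_primary_ions(hits[0, ])
  expect_length(empty$metabolites, 0L)
  expect_equal(nrow(empty$hits), 0L)
})
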