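test_that("monoisotopic masses match brute-force isotope sums", {
  # independent oracle: explicit sums of most-abundant-isotope masses
  expect_equal(monoisotopic_mass("C5H9NO2"),
               5 * 12 + 9 * 1.007825 + 14.003074 + 2 * 15.994915,
               tolerance = 1e-9)
  expect_equal(round(monoisotopic_mass("C5H9NO2"), 4), 115.0633)
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("C6H4Br2O"),
               6 * 12 + 4 * 1.007825 + 2 * 78.918338 + 15.994915,
               tolerance = 1e-9)
})

test_that("formula parsing handles counts, repeats and bad input", {
  expect_equal(parse_formula("C5H9NO2"),
               c(C = 5, H = 9, N = 1, O = 2)[c("C", "H", "N", "O")])
  # repeated element symbols accumulate
  expect_equal(unname(parse_formula("CH3CH3")["C"]), 2)
  expect_equal(unname(parse_formula("CH3CH3")["H"]), 6)
  expect_error(parse_formula("C5X2"), "unknown element")
  expect_error(parse_formula("5C"), "cannot parse")
})

test_that("mass additivity holds for disjoint formula merges", {
  set.seed(3)
  els <- c("C", "H", "N", "O", "S", "Br")
  for (i in 1:10) {
    a <- setNames(sample(0:9, 6, replace = TRUE), els)
    b <- setNames(sample(0:9, 6, replace = TRUE), els)
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-10)
  }
})

test_that("deprotonated m/z reproduces the printed amino-acid and phenolic ions", {
  expect_equal(round(deprotonated_mz("C5H9NO2"), 4), 114.0555)  # proline
  expect_equal(round(deprotonated_mz("C5H9NO4"), 4), 146.0453)  # glutamate
  expect_equal(round(deprotonated_mz("C8H8O4"), 4), 167.0344)   # vanillic
  expect_equal(round(deprotonated_mz("C15H12O5"), 4), 271.0606) # naringenin
  expect_error(deprotonated_mz("CO2"), "no hydrogen")
})

test_that("the bundled compound library loads completely", {
  lib <- sf_compounds()
  expect_equal(nrow(lib), 79)
  expect_equal(lib$index, 1:79)
  expect_equal(sum(lib$first_in_sf), 12)     # first-time identifications
  expect_setequal(unique(lib$class),
                  c("phenolic acid", "flavonoid", "tannin", "terpene",
                    "carboxylic acid", "fatty acid", "amino acid", "sugar",
                    "other"))
  expect_type(lib$fragments, "list")
  expect_equal(lib$fragments[[6]], c(215.00, 179.03, 135.04))
  expect_true(all(is.finite(lib$theory_mz)))
})

test_that("the discrepancy report surfaces printed-mass inconsistencies", {
  rep_ <- library_discrepancies()
  expect_equal(nrow(rep_), 79)
  # suspect formulas are always flagged
  expect_true(all(rep_$flagged[rep_$index %in% c(14, 78)]))
  # the positive-mode-like observed mass of azelaic acid is ~1 Da off
  expect_gt(rep_$obs_delta_mda[rep_$index == 35], 900)
  # gallic acid: printed calculated mass differs from theory by < 1 mDa
  expect_lt(abs(rep_$calc_delta_mda[rep_$index == 1]), 1)
})

test_that("peak matching ranks by ppm error with the theory denominator", {
  lib <- sf_compounds()
  hit <- match_peak(114.0555, lib, ppm_tol = 5)
  expect_equal(hit$name[1], "L-Proline")
  expect_lt(abs(hit$ppm_error[1]), 5)
  hit2 <- match_peak(271.0606, lib, ppm_tol = 5)
  expect_true("Naringenin" %in% hit2$name)
  # empty library -> empty result, not an error
  empty <- lib[0, ]
  expect_equal(nrow(match_peak(200, empty)), 0)
  # ppm uses theory as denominator
  th <- deprotonated_mz("C5H9NO2")
  expect_equal(hit$ppm_error[hit$name == "L-Proline"],
               1e6 * (114.0555 - th) / th, tolerance = 1e-9)
  expect_error(match_peak(114, lib, ppm_tol = 0), "ppm_tol")
  expect_error(match_peak(-5, lib), "positive")
})

test_that("neutral-loss labelling reproduces the reported fragmentations", {
  # glycoside: losing the sugar moiety (162 Da)
  r1 <- annotate_losses(309.0974, 147.04)
  expect_equal(r1$label, "hexose")
  # sulfated phenolic: CO2 off the precursor, then SO3 between fragments
  r2 <- annotate_losses(258.9912, c(215.00, 135.04))
  expect_equal(r2$label[r2$from_mz == 258.9912 & r2$to_mz == 215.00], "CO2")
  expect_equal(r2$label[r2$from_mz == 215.00 & r2$to_mz == 135.04], "SO3")
  # fragment equal to the precursor: zero loss, no row
  expect_equal(nrow(annotate_losses(200, 200)), 0)
  # unmatched differences come back labelled unknown
  r3 <- annotate_losses(300, 123.456)
  expect_equal(r3$label, "unknown")
  expect_error(annotate_losses(100, 150), "exceed")
  expect_error(annotate_losses(100, 50, tol_da = 0), "tol_da")
})
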