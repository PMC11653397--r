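# Formula arithmetic, exact masses, ppm errors and the rule engine.

test_that("monoisotopic masses come from the pinned principal-isotope table", {
  expect_identical(monoisotopicMass(formula_make(C = 1)), 12)
  # hand-sum: 12*12 + 5*1.00782503 + 5*34.96885268
  expect_equal(monoisotopicMass(formula_parse("C12H5Cl5")),
               323.88338855, tolerance = 1e-8)
  expect_identical(monoisotopicMass(formula_make()), 0)
  expect_error(monoisotopicMass(formula_make(Xx = 1)), "Xx")
})

test_that("formula arithmetic is count-wise and never goes negative", {
  a <- formula_parse("C12H5Cl5")
  b <- formula_make(O = 1)
  expect_true((a + b) == formula_parse("C12H5Cl5O"))
  expect_true((a + b) - b == a)
  expect_error(b - a, "negative")
  # removing an element leaves count 0, dropped from storage
  expect_true((a - formula_make(Cl = 5)) == formula_parse("C12H5"))
  expect_identical(formulaToString(formula_parse("OC12Cl5H5")), "C12H5Cl5O")
})

test_that("deprotonated-ion m/z includes the electron mass", {
  expect_equal(ionMz(formula_parse("C12H5Cl5O"), -1), 338.87103,
               tolerance = 2e-5)
  expect_equal(ionMz(formula_parse("C12H7Cl3O"), -1), 270.94897,
               tolerance = 2e-5)
  expect_equal(ionMz(formula_parse("C12H5Cl5O4S"), -1), 418.82784,
               tolerance = 2e-5)
  # guard: dropping the electron term shifts every anion by ~ -0.00055 Da
  no_electron <- monoisotopicMass(ionFormula(formula_parse("C12H5Cl5O")))
  expect_equal(ionMz(formula_parse("C12H5Cl5O")) - no_electron,
               0.00054858, tolerance = 1e-8)
  expect_gt(abs(no_electron - 338.87103), 2e-5)
  expect_error(ionMz(formula_make(C = 2), -1), "H")
  expect_error(ionMz(formula_parse("C12H5Cl5O"), 0), "charge")
})

test_that("ppm error follows the signed relative-difference formula", {
  expect_identical(ppmError(338.87103, 338.87103), 0)
  expect_equal(ppmError(338.87104, 338.87103), 0.0295, tolerance = 1e-3)
  expect_equal(ppmError(418.82768, 418.82784), -0.382, tolerance = 1e-3)
  expect_error(ppmError(100, 0), "positive")
  # antisymmetric up to the change of denominator
  for (x in c(150.1, 338.87103, 999.5)) {
    expect_identical(ppmError(x, x), 0)
    expect_equal(ppmError(x * (1 + 1e-6), x), -ppmError(x, x * (1 + 1e-6)),
                 tolerance = 1e-5)
  }
})

test_that("applyRule applies deltas under constraints", {
  rules <- defaultRules()
  p <- formula_parse("C12H5Cl5")
  expect_true(applyRule(p, rules$OX) == formula_parse("C12H5Cl5O"))
  expect_true(applyRule(formula_parse("C12H5Cl5O"), rules$DECHLOR) ==
                formula_parse("C12H6Cl4O"))
  # inverse delta restores the original formula
  oh <- applyRule(p, rules$OX)
  expect_true(oh - formula_make(O = 1) == p)
  # dechlorination stops when no Cl is left
  f <- p
  for (i in 1:5) f <- applyRule(f, defaultRules(dechlor_max = 5)$DECHLOR)
  expect_false("Cl" %in% names(f@counts))
  expect_error(applyRule(f, defaultRules(dechlor_max = 9)$DECHLOR),
               "DECHLOR")
  # methylation needs a catechol (two prior oxidations)
  expect_error(applyRule(p, rules$METH), "METH")
  expect_true(applyRule(p, rules$METH, provenance = c("OX", "OX")) ==
                formula_parse("C13H7Cl5"))
})

test_that("suspect enumeration covers the full metabolite class catalogue", {
  sl <- enumerateSuspects()
  tab <- candidates(sl)
  expect_setequal(sort(unique(tab$class_id[!is.na(tab$class_id)])),
                  c("1.1", "1.2", "2", "3", "4", "5", "6", "7", "8"))
  want_ions <- c("C12H4Cl5O", "C12H4Cl5O4S", "C12H4Cl5O5S", "C13H6Cl5O2",
                 "C13H6Cl5O3", "C12H4Cl5O3S", "C12H6Cl3O", "C12H5Cl4O",
                 "C12H6Cl3O2")
  expect_true(all(want_ions %in% tab$ion_formula))
  expect_false(anyDuplicated(tab$neutral_formula) > 0)
  # methylated catechol chain reaches the expected ion mass
  meo <- tab[which(tab$class_id == "3"), ]
  expect_identical(meo$ion_formula, "C13H6Cl5O2")
  expect_equal(meo$theoretical_mz, 368.88159, tolerance = 2e-5)
})

test_that("enumeration degenerate cases and provenance replay", {
  p <- formula_parse("C12H5Cl5")
  only_parent <- enumerateSuspects(p, rules = list())
  expect_identical(length(only_parent), 1L)
  expect_identical(candidates(only_parent)$neutral_formula, "C12H5Cl5")
  ox1 <- enumerateSuspects(p, rules = defaultRules()["OX"], max_chain = 1)
  expect_identical(length(ox1), 2L)  # parent + OH-PCB95
  expect_equal(candidates(ox1)$theoretical_mz[
    which(candidates(ox1)$class_id == "1.1")], 338.87103,
    tolerance = 2e-5)
  # each provenance chain replays from the parent to the stated formula
  tab <- candidates(enumerateSuspects())
  rules <- defaultRules()
  for (i in seq_len(nrow(tab))) {
    prov <- strsplit(tab$provenance[i], ",")[[1]]
    f <- p
    for (j in seq_along(prov))
      f <- applyRule(f, rules[[prov[j]]], provenance = prov[seq_len(j - 1)])
    expect_true(f == formula_parse(tab$neutral_formula[i]))
  }
})

test_that("enumeration output is invariant to rule ordering", {
  key <- function(sl) {
    tab <- candidates(sl)
    sort(paste(tab$neutral_formula, tab$class_id))
  }
  expect_identical(key(enumerateSuspects(rules = defaultRules())),
                   key(enumerateSuspects(rules = rev(defaultRules()))))
})

test_that("expected neutral losses are computed from atomic masses", {
  tab <- candidates(enumerateSuspects())
  get <- function(cl) tab$expected_losses[match(cl, tab$class_id)]
  expect_identical(get("1.1"), "HCl")
  expect_identical(get("1.2"), "SO3")
  expect_identical(get("3"), "CH3")
  expect_identical(get("5"), "")    # ring sulfonate: no diagnostic loss
  expect_equal(neutralLossMass("HCl"), 35.97668, tolerance = 1e-5)
  expect_equal(neutralLossMass("SO3"), 79.95682, tolerance = 1e-5)
  expect_equal(neutralLossMass("CH3"), 15.02348, tolerance = 1e-5)
  # consistency with the reported HCl-loss fragment of the phenol
  expect_equal(338.87103 - neutralLossMass("HCl"), 302.89438,
               tolerance = 1e-4)
})

test_that("suspect lists round-trip through CSV", {
  sl <- enumerateSuspects()
  path <- withr::local_tempfile(fileext = ".csv")
  writeSuspects(sl, path)
  back <- readSuspects(path)
  expect_equal(candidates(back)$theoretical_mz,
               candidates(sl)$theoretical_mz, tolerance = 1e-9)
  expect_identical(candidates(back)$class_id, candidates(sl)$class_id)
  expect_true(back@parent == sl@parent)
})
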