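# Matching, confirmation, normalization and the majority-detection rule.

test_that("peak lists round-trip through TSV and reject malformed rows", {
  peaks <- make_peaks(mz = c(338.8711, 340.8681), rt = c(5, 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeakLists(peaks, path)
  back <- readPeakLists(path)
  expect_equal(back$mz, peaks$mz, tolerance = 1e-9)
  expect_identical(nrow(back), 2L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(out <- readPeakLists(empty), "empty")
  expect_identical(nrow(out), 0L)

  bad <- peaks; bad$mz[2] <- -1
  writePeakLists(bad, path)
  expect_error(readPeakLists(path), "line")
  expect_error(readPeakLists(withr::local_tempfile(fileext = ".tsv")),
               "not found|no peak")
})

test_that("candidates match within the ppm tolerance and not outside", {
  sl <- make_suspects(data.frame(theoretical_mz = 338.87103))
  th <- 338.87103
  hit <- matchCandidates(make_peaks(th * (1 + 2e-6)), sl)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$delta_ppm, 2.00, tolerance = 1e-6)
  miss <- matchCandidates(make_peaks(th * (1 + 8e-6)), sl)
  expect_identical(nrow(miss), 0L)
  expect_error(matchCandidates(make_peaks(th), sl, tolerance_ppm = 0),
               "positive")
})

test_that("rt-contiguous peaks form one feature with the apex recorded", {
  sl <- make_suspects(data.frame(theoretical_mz = 338.87103))
  pk <- make_peaks(rep(338.87103, 4), intensity = c(1, 9, 4, 6) * 1e5,
                   rt = c(5.0, 5.1, 5.2, 7.0))
  rec <- matchCandidates(pk, sl)
  expect_identical(nrow(rec), 2L)   # gap 1.8 min splits a second feature
  expect_equal(rec$raw_intensity, c(9e5, 6e5))
  expect_equal(rec$rt, c(5.1, 7.0))
})

test_that("two near-isobaric candidates sharing one peak are both flagged", {
  th <- 338.87103
  tab <- data.frame(name = c("a", "b"),
                    neutral_formula = c("C12H5Cl5O", "C12H5Cl5O"),
                    theoretical_mz = c(th, th * (1 + 3e-6)),
                    class_id = c("1.1", NA))
  sl <- make_suspects(tab)
  rec <- matchCandidates(make_peaks(th * (1 + 1.5e-6)), sl)
  expect_identical(nrow(rec), 2L)
  expect_true(all(rec$ambiguous))
})

test_that("isotope confirmation keeps full envelopes and drops decoys", {
  sl <- enumerateSuspects()
  tab <- candidates(sl)[candidates(sl)$class_id %in% "1.1", , drop = FALSE]
  sl1 <- new("SuspectList", candidates = tab, parent = sl@parent)
  env <- isotopeEnvelope(formula_parse("C12H5Cl5O"))
  env <- env[env$rel_intensity >= 1, ]
  full <- make_peaks(env$mz, intensity = env$rel_intensity * 1e4, rt = 5)
  rec <- matchCandidates(full, sl1)
  conf <- confirmIsotopes(rec, full)
  expect_identical(nrow(conf$confirmed), 1L)
  expect_gte(conf$confirmed$isotope_score, 0.99)

  mono_only <- make_peaks(tab$theoretical_mz, intensity = 1e6, rt = 5)
  conf2 <- confirmIsotopes(matchCandidates(mono_only, sl1), mono_only)
  expect_identical(nrow(conf2$confirmed), 0L)
  expect_lt(conf2$audit$isotope_score, 0.95)

  # chlorine-free contaminant at the candidate m/z: wrong M+1/M+2 shape
  cfree <- isotopeEnvelope(formula_make(C = 24, H = 22, O = 6))
  shift <- tab$theoretical_mz - cfree$mz[1]
  decoy <- make_peaks(cfree$mz + shift,
                      intensity = cfree$rel_intensity * 1e4, rt = 5)
  conf3 <- confirmIsotopes(matchCandidates(decoy, sl1), decoy)
  expect_identical(nrow(conf3$confirmed), 0L)
})

test_that("fragment confirmation sets the confidence level", {
  sl <- enumerateSuspects()
  tab <- candidates(sl)[candidates(sl)$class_id %in% "1.1", , drop = FALSE]
  th <- tab$theoretical_mz
  rec <- data.frame(class_id = "1.1", candidate = tab$name,
                    neutral_formula = tab$neutral_formula,
                    theoretical_mz = th, expected_losses = "HCl",
                    sample_id = "S1", rt = 5, measured_mz = th,
                    delta_ppm = 0, raw_intensity = 1e6, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  frag <- make_peaks(302.89435, rt = 5, level = "MS2", precursor_mz = th)
  out <- confirmFragments(rec, frag)
  expect_identical(out$confidence_level, 2L)
  expect_identical(out$fragments_confirmed, "HCl")

  out2 <- confirmFragments(rec, frag[0, ])   # no MS2 scans at all
  expect_identical(out2$confidence_level, 3L)

  frag_off <- make_peaks(302.89435 * (1 + 20e-6), rt = 5, level = "MS2",
                         precursor_mz = th)
  out3 <- confirmFragments(rec, frag_off)
  expect_identical(out3$confidence_level, 3L)
})

test_that("relative abundance divides by PFOS signal and wet mass", {
  rec <- data.frame(sample_id = c("S1", "S2"), raw_intensity = c(1e6, 2e6))
  meta <- data.frame(sample_id = "S1", sex = "M", genotype = "WT",
                     sample_mass = 1, pfos_intensity = 1e6,
                     is_blank = FALSE)
  expect_warning(out <- relativeAbundance(rec, meta), "S2")
  expect_identical(out$relative_abundance, 1)
  meta2 <- rbind(meta, data.frame(sample_id = "S2", sex = "F",
                                  genotype = "WT", sample_mass = 0.025,
                                  pfos_intensity = 1e6, is_blank = FALSE))
  out2 <- relativeAbundance(rec, meta2)
  expect_equal(out2$relative_abundance, c(1, 80))
  meta2$pfos_intensity <- meta2$pfos_intensity * 2
  expect_equal(relativeAbundance(rec, meta2)$relative_abundance,
               c(0.5, 40))
})

test_that("the majority rule retains strictly more than half", {
  mk <- function(n_detected) {
    data.frame(class_id = "1.1", candidate = "OH-PCB95",
               neutral_formula = "C12H5Cl5O", theoretical_mz = 338.87103,
               sample_id = paste0("S", seq_len(n_detected)),
               rt = 7.7, measured_mz = 338.87103, delta_ppm = 0,
               raw_intensity = 1e6, stringsAsFactors = FALSE)
  }
  expect_true(frequencyFilter(mk(16), 30)$retained)
  expect_false(frequencyFilter(mk(15), 30)$retained)
  expect_identical(nrow(frequencyFilter(mk(1)[0, ], 30)), 0L)
  expect_error(frequencyFilter(mk(1), 0), "n_samples")
})

test_that("screening output is invariant to peak and sample ordering", {
  cfg <- small_config()
  st <- generateStudy(cfg, seed = 7)
  sl <- enumerateSuspects()
  base <- screenStudy(st$peaks, st$meta, sl)
  shuf <- st$peaks[sample(nrow(st$peaks)), ]
  meta_shuf <- st$meta[sample(nrow(st$meta)), ]
  alt <- screenStudy(shuf, meta_shuf, sl)
  ord <- function(x) {
    x <- x[order(x$candidate, x$sample_id, x$rt), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(base$detections), ord(alt$detections), tolerance = 1e-12)
  expect_equal(base$report$frequency[order(base$report$candidate)],
               alt$report$frequency[order(alt$report$candidate)])
})
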