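# The synthetic-study generator: determinism, closed-loop recovery and
# inverse-construction guarantees.

test_that("identical seeds give identical studies", {
  cfg <- small_config()
  a <- generateStudy(cfg, seed = 42)
  b <- generateStudy(cfg, seed = 42)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c <- generateStudy(cfg, seed = 43)
  expect_false(identical(a$peaks, c$peaks))
  ga <- generateGcTables(cfg, seed = 42)
  gb <- generateGcTables(cfg, seed = 42)
  expect_identical(ga$areas, gb$areas)
  expect_identical(ga$truth$concentrations, gb$truth$concentrations)
})

test_that("a noise-free all-present study is recovered exactly by the screen", {
  cfg <- small_config(mass_error_ppm = 0, rt_jitter_sd = 0,
                      intensity_noise_sdlog = 0)
  st <- generateStudy(cfg, seed = 5)
  scr <- screenStudy(st$peaks, st$meta, enumerateSuspects())
  rep <- scr$report
  planted <- sort(unique(cfg$species$class_id))
  expect_setequal(rep$class_id[rep$retained & !is.na(rep$class_id)],
                  planted)
  expect_identical(sum(rep$retained & is.na(rep$class_id)), 0L)
  expect_true(all(abs(scr$detections$delta_ppm) < 1e-9))
})

test_that("a species planted in a minority of samples is dropped", {
  cfg <- small_config(presence_prob = c(0.4, rep(1, 14)),
                      n_per_group = 5L)
  st <- generateStudy(cfg, seed = 12)
  n_present <- sum(st$truth$present[st$truth$class_id == "1.1" &
                                      !grepl("BLANK", st$truth$sample_id)])
  n_samples <- sum(!st$meta$is_blank)
  expect_lte(n_present / n_samples, 0.5)   # seed-fixed construction
  scr <- screenStudy(st$peaks, st$meta, enumerateSuspects())
  r11 <- scr$report[scr$report$class_id %in% "1.1", ]
  expect_false(any(r11$retained))
  others <- scr$report[!is.na(scr$report$class_id) &
                         scr$report$class_id != "1.1", ]
  expect_true(all(others$retained))
})

test_that("decoys never fall within the exclusion window of a suspect", {
  cfg <- small_config()
  st <- generateStudy(cfg, seed = 3)
  suspect_mz <- candidates(enumerateSuspects())$theoretical_mz
  planted_rt <- cfg$species$rt
  # peaks far from every planted feature rt are decoys (or PFOS)
  decoyish <- st$peaks[st$peaks$level == "MS1" &
    !vapply(st$peaks$rt_min, function(r)
      any(abs(r - c(planted_rt, 6.8)) < 0.4), logical(1)), ]
  ppm_min <- vapply(decoyish$mz, function(m)
    min(abs(m - suspect_mz) / suspect_mz * 1e6), numeric(1))
  expect_true(all(ppm_min > 25))
})

test_that("noise-free GC tables invert to the planted concentrations", {
  cfg <- small_config()
  gc <- generateGcTables(cfg, seed = 8, noise_sdlog = 0)
  rrf <- computeRRF(gc$standards)
  known <- gc$analyte_groups$analyte[gc$analyte_groups$has_standard]
  res <- quantifyAreas(gc$areas[gc$areas$analyte %in%
                                  c(known, "PFOS_IS"), ],
                       rrf, gc$is_amount, gc$meta, gc$recoveries,
                       gc$surrogate_map)
  m <- merge(res, gc$truth$concentrations)
  expect_equal(m$concentration, m$true_conc, tolerance = 1e-9)
  # unknowns through the group-average RRF are exact too (by construction
  # the unknowns respond at the group average)
  unk <- gc$analyte_groups[!gc$analyte_groups$has_standard, ]
  res_u <- do.call(rbind, lapply(seq_len(nrow(unk)), function(i)
    estimateUnknown(gc$areas[gc$areas$analyte %in%
                               c(unk$analyte[i], "PFOS_IS"), ],
                    rrf, unk$group[i], gc$is_amount, gc$meta,
                    gc$recoveries, gc$surrogate_map)))
  mu <- merge(res_u, gc$truth$concentrations)
  expect_equal(mu$concentration, mu$true_conc, tolerance = 1e-9)
})

test_that("skipping recovery correction biases by exactly the recovery", {
  cfg <- small_config()
  gc <- generateGcTables(cfg, seed = 8, noise_sdlog = 0)
  rrf <- computeRRF(gc$standards)
  res_unc <- quantifyAreas(gc$areas[gc$areas$analyte %in%
                                      c("PCB95", "PFOS_IS"), ],
                           rrf, gc$is_amount, gc$meta)
  m <- merge(res_unc, gc$truth$concentrations)
  rec <- gc$recoveries$recovery[gc$recoveries$surrogate == "PCB117"][
    match(m$sample_id,
          gc$recoveries$sample_id[gc$recoveries$surrogate == "PCB117"])]
  expect_equal(m$concentration / m$true_conc, rec, tolerance = 1e-9)
})

test_that("atropisomer pairs carry the configured group EFs", {
  cfg <- small_config()
  gc <- generateGcTables(cfg, seed = 2)
  ef <- computeEF(gc$atropisomers$a_e1, gc$atropisomers$a_e2)
  expect_equal(ef, gc$atropisomers$true_ef, tolerance = 1e-12)
  cfg_rac <- small_config(ef_by_group = c(M_WT = 0.5, F_WT = 0.5,
                                          M_KO = 0.5, F_KO = 0.5,
                                          M_KI = 0.5, F_KI = 0.5))
  gc2 <- generateGcTables(cfg_rac, seed = 2)
  expect_equal(computeEF(gc2$atropisomers$a_e1, gc2$atropisomers$a_e2),
               rep(0.5, nrow(gc2$atropisomers)))
})

test_that("synthetic peak lists round-trip through the TSV reader", {
  cfg <- small_config(n_decoys = 10L)
  st <- generateStudy(cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeakLists(st$peaks, path)
  back <- readPeakLists(path)
  expect_equal(back$mz, st$peaks$mz, tolerance = 1e-12)
  expect_identical(back$sample_id, st$peaks$sample_id)
})
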