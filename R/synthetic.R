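## Synthetic-study generator: renders complete studies -- MS1/MS2 peak
## lists, GC area tables, atropisomer pairs, blanks and metadata -- with
## full ground truth, so every pipeline stage can be exercised end to end
## without any instrument data.

#' Default planted metabolite species
#'
#' The 15 planted species: one row per detected chromatographic species
#' of the named metabolite classes (several classes elute as 2-3
#' positional isomers), with representative retention times.
#'
#' @param suspects A [SuspectList-class] providing formulas and losses.
#' @return data.frame `species_id`, `class_id`, `name`, `neutral_formula`,
#'   `theoretical_mz`, `expected_losses`, `rt`.
#' @export
defaultSpecies <- function(suspects = enumerateSuspects()) {
  rt_by_class <- list(`1.1` = 7.77, `1.2` = c(6.51, 6.67),
                      `2` = c(5.78, 6.87, 7.01), `3` = c(7.88, 8.00),
                      `4` = 6.73, `5` = 5.96, `6` = 7.68,
                      `7` = c(6.48, 7.69, 7.80), `8` = 7.60)
  cand <- candidates(suspects)
  cand <- cand[!is.na(cand$class_id), , drop = FALSE]
  rows <- lapply(names(rt_by_class), function(cl) {
    c_row <- cand[cand$class_id == cl, , drop = FALSE]
    stopifnot(nrow(c_row) == 1L)
    rts <- rt_by_class[[cl]]
    data.frame(species_id = paste0(cl, letters[seq_along(rts)]),
               class_id = cl, name = c_row$name,
               neutral_formula = c_row$neutral_formula,
               theoretical_mz = c_row$theoretical_mz,
               expected_losses = c_row$expected_losses,
               rt = rts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic study configuration
#'
#' Defaults emulate the study design: six sex x genotype groups of six
#' mice, 15 planted metabolite species across the named classes,
#' log-normal abundances with multiplicative group effects, 1.5 ppm
#' Gaussian mass error, PRM fragments emitted for the fragment-bearing
#' classes (1.1-4) only, decoy peaks kept at least 25 ppm from any
#' suspect m/z, a PFOS volume-corrector ion in every run, and parallel
#' blanks.
#'
#' @param n_per_group Samples per sex x genotype group.
#' @param species Planted-species table ([defaultSpecies()]).
#' @param presence_prob Per-species probability of being planted in a
#'   sample (recycled; default 1).
#' @param abundance_median,abundance_gsd Log-normal intensity parameters.
#' @param effect_sex_F,effect_KO,effect_KI Multiplicative group effects
#'   on the abundance median.
#' @param mass_error_ppm Gaussian m/z error SD in ppm.
#' @param rt_jitter_sd Retention-time jitter SD, minutes.
#' @param intensity_noise_sdlog Multiplicative peak-intensity noise
#'   (sdlog).
#' @param ms2_prob Named per-class fragment-emission probabilities.
#' @param n_decoys Decoy peaks per sample.
#' @param decoy_exclusion_ppm Decoys avoid suspect m/z by at least this.
#' @param ef_by_group Named per-group true enantiomeric fractions.
#' @param n_blanks Parallel blank samples.
#' @param blank_level Fraction of the study median abundance planted in
#'   blanks (0 = clean blanks).
#' @param gc_noise_sdlog Multiplicative noise on GC areas (0.1 = 10%).
#' @return Named list of settings for [generateStudy()] /
#'   [generateGcTables()].
#' @export
studyConfig <- function(n_per_group = 6L,
                        species = defaultSpecies(),
                        presence_prob = 1,
                        abundance_median = 1e6, abundance_gsd = 2.5,
                        effect_sex_F = 1.5, effect_KO = 2, effect_KI = 0.7,
                        mass_error_ppm = 1.5, rt_jitter_sd = 0.05,
                        intensity_noise_sdlog = 0.05,
                        ms2_prob = c(`1.1` = 1, `1.2` = 1, `2` = 1,
                                     `3` = 1, `4` = 1, `5` = 0, `6` = 0,
                                     `7` = 0, `8` = 0),
                        n_decoys = 200L, decoy_exclusion_ppm = 25,
                        ef_by_group = c(M_WT = 0.44, F_WT = 0.39,
                                        M_KO = 0.45, F_KO = 0.42,
                                        M_KI = 0.43, F_KI = 0.41),
                        n_blanks = 3L, blank_level = 0,
                        gc_noise_sdlog = 0.1) {
  stopifnot(n_per_group >= 1L, mass_error_ppm >= 0,
            all(presence_prob >= 0 & presence_prob <= 1),
            all(ms2_prob >= 0 & ms2_prob <= 1))
  species$presence_prob <- rep_len(presence_prob, nrow(species))
  list(n_per_group = as.integer(n_per_group), species = species,
       abundance_median = abundance_median, abundance_gsd = abundance_gsd,
       effect_sex_F = effect_sex_F, effect_KO = effect_KO,
       effect_KI = effect_KI, mass_error_ppm = mass_error_ppm,
       rt_jitter_sd = rt_jitter_sd,
       intensity_noise_sdlog = intensity_noise_sdlog, ms2_prob = ms2_prob,
       n_decoys = as.integer(n_decoys),
       decoy_exclusion_ppm = decoy_exclusion_ppm,
       ef_by_group = ef_by_group, n_blanks = as.integer(n_blanks),
       blank_level = blank_level, gc_noise_sdlog = gc_noise_sdlog)
}

.group_multiplier <- function(config, sex, genotype) {
  m <- 1
  if (sex == "F") m <- m * config$effect_sex_F
  if (genotype == "KO") m <- m * config$effect_KO
  if (genotype == "KI") m <- m * config$effect_KI
  m
}

.make_meta <- function(config) {
  grid <- expand.grid(sex = c("M", "F"), genotype = c("WT", "KO", "KI"),
                      rep = seq_len(config$n_per_group),
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%d", grid$sex, grid$genotype, grid$rep),
    sex = grid$sex, genotype = grid$genotype,
    sample_mass = stats::runif(nrow(grid), 0.018, 0.033),
    pfos_intensity = NA_real_, is_blank = FALSE, stringsAsFactors = FALSE)
  if (config$n_blanks > 0L) {
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("BLANK_%d", seq_len(config$n_blanks)),
      sex = "M", genotype = "WT",
      sample_mass = stats::runif(config$n_blanks, 0.018, 0.033),
      pfos_intensity = NA_real_, is_blank = TRUE,
      stringsAsFactors = FALSE))
  }
  meta
}

#' Generate a synthetic LC-HRMS study
#'
#' Every planted species is rendered as its full theoretical isotope
#' envelope (the peaks above 1% relative intensity) with multiplicative
#' intensity noise and Gaussian ppm mass error at a jittered retention
#' time; MS2 scans carry the expected neutral-loss fragments with the
#' configured per-class probability; a PFOS volume-corrector ion is
#' planted in every run; decoy peaks are placed uniformly but never
#' within the exclusion window of any suspect m/z. Identical seeds give
#' identical output.
#'
#' @param config A [studyConfig()] list.
#' @param seed Integer random seed (all randomness flows from it).
#' @return list: `peaks` (MS1+MS2 data.frame), `meta`, `truth`
#'   (per sample x species ground truth), `config`, `seed`.
#' @export
generateStudy <- function(config = studyConfig(), seed = 1L) {
  set.seed(seed)
  meta <- .make_meta(config)
  species <- config$species
  env_cache <- lapply(stats::setNames(unique(species$neutral_formula),
                                      unique(species$neutral_formula)),
                      function(f) {
    e <- isotopeEnvelope(formula_parse(f))
    e[e$rel_intensity >= 1, , drop = FALSE]
  })
  pfos_mz <- ionMz(formula_make(.PFOS_NEUTRAL))
  suspect_mz <- c(candidates(enumerateSuspects())$theoretical_mz, pfos_mz)
  sdlog_ab <- log(config$abundance_gsd)
  ppm_sd <- config$mass_error_ppm

  peaks <- list(); truth <- list()
  for (k in seq_len(nrow(meta))) {
    sid <- meta$sample_id[k]
    mult <- if (meta$is_blank[k]) config$blank_level else
      .group_multiplier(config, meta$sex[k], meta$genotype[k])
    pfos_int <- stats::rlnorm(1, log(1e7), 0.2)
    meta$pfos_intensity[k] <- pfos_int
    peaks[[length(peaks) + 1L]] <- data.frame(
      sample_id = sid, level = "MS1", precursor_mz = NA_real_,
      rt_min = 6.80 + stats::rnorm(1, 0, config$rt_jitter_sd),
      mz = pfos_mz * (1 + stats::rnorm(1, 0, ppm_sd) * 1e-6),
      intensity = pfos_int, stringsAsFactors = FALSE)

    for (s in seq_len(nrow(species))) {
      present <- mult > 0 &&
        stats::runif(1) < species$presence_prob[s]
      base_int <- if (present)
        config$abundance_median * mult *
          stats::rlnorm(1, 0, sdlog_ab) else 0
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sid, species_id = species$species_id[s],
        class_id = species$class_id[s], name = species$name[s],
        present = present, true_intensity = base_int,
        stringsAsFactors = FALSE)
      if (!present) next
      env <- env_cache[[species$neutral_formula[s]]]
      rt <- species$rt[s] + stats::rnorm(1, 0, config$rt_jitter_sd)
      peaks[[length(peaks) + 1L]] <- data.frame(
        sample_id = sid, level = "MS1", precursor_mz = NA_real_,
        rt_min = rt,
        mz = env$mz * (1 + stats::rnorm(nrow(env), 0, ppm_sd) * 1e-6),
        intensity = base_int * env$rel_intensity / 100 *
          stats::rlnorm(nrow(env), 0, config$intensity_noise_sdlog),
        stringsAsFactors = FALSE)
      losses <- strsplit(species$expected_losses[s], ",")[[1]]
      losses <- losses[nzchar(losses)]
      p_ms2 <- config$ms2_prob[species$class_id[s]]
      if (length(losses) && !is.na(p_ms2) && stats::runif(1) < p_ms2) {
        th <- species$theoretical_mz[s]
        fmz <- th - vapply(losses, neutralLossMass, numeric(1))
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample_id = sid, level = "MS2", precursor_mz = th,
          rt_min = rt,
          mz = fmz * (1 + stats::rnorm(length(fmz), 0, ppm_sd) * 1e-6),
          intensity = base_int * 0.1 *
            stats::rlnorm(length(fmz), 0, config$intensity_noise_sdlog),
          stringsAsFactors = FALSE)
      }
    }

    if (config$n_decoys > 0L) {
      mz <- numeric(0)
      while (length(mz) < config$n_decoys) {
        cand_mz <- stats::runif(config$n_decoys, 150, 1000)
        ok <- vapply(cand_mz, function(m)
          all(abs(m - suspect_mz) / suspect_mz * 1e6 >
                config$decoy_exclusion_ppm), logical(1))
        mz <- c(mz, cand_mz[ok])
      }
      mz <- mz[seq_len(config$n_decoys)]
      peaks[[length(peaks) + 1L]] <- data.frame(
        sample_id = sid, level = "MS1", precursor_mz = NA_real_,
        rt_min = stats::runif(config$n_decoys, 0.5, 10),
        mz = mz,
        intensity = stats::rlnorm(config$n_decoys, log(5e4), 1),
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, peaks)
  peaks <- peaks[order(peaks$sample_id, peaks$level, peaks$rt_min,
                       peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, meta = meta, truth = do.call(rbind, truth),
       config = config, seed = seed)
}

#' Generate synthetic GC area tables with ground truth
#'
#' Constructs calibration-standard and sample area tables by inverting
#' the internal-standard quantification model: in the noise-free case
#' [quantifyAreas()] recovers the planted concentrations exactly.
#' Includes surrogate recoveries, atropisomer area pairs drawn from the
#' configured per-group enantiomeric fractions, and method/tissue blanks.
#'
#' @param config A [studyConfig()] list.
#' @param seed Integer random seed.
#' @param noise_sdlog Multiplicative area noise (sdlog); defaults to
#'   `config$gc_noise_sdlog`. 0 gives the exact inverse construction.
#' @return list: `areas`, `standards`, `recoveries`, `surrogate_map`,
#'   `meta`, `atropisomers`, `blanks`, `truth` (planted concentrations,
#'   RRFs, recoveries, EFs), `is_amount`.
#' @export
generateGcTables <- function(config = studyConfig(), seed = 1L,
                             noise_sdlog = config$gc_noise_sdlog) {
  set.seed(seed + 1L)
  meta <- .make_meta(config)
  meta <- meta[!meta$is_blank, , drop = FALSE]

  analytes <- data.frame(
    analyte = c("PCB95", "4-95", "4p-95", "5-95", "4,5-95",
                "X1-95", "Y1-95", "Y2-95", "Y3-95"),
    group = c("parent", "monoOH", "monoOH", "monoOH", "diOH",
              "monoOH", "diOH", "diOH", "diOH"),
    has_standard = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                     FALSE, FALSE, FALSE, FALSE),
    surrogate = c("PCB117", rep("4p-159", 8)),
    median_conc = c(80, 450, 400, 350, 500, 300, 420, 380, 360),
    stringsAsFactors = FALSE)

  true_rrf <- stats::setNames(stats::runif(nrow(analytes), 0.8, 1.2),
                              analytes$analyte)
  ## unknowns respond at their transition group's average standard RRF,
  ## so the group-average estimate is exact in the noise-free case
  for (g in c("monoOH", "diOH")) {
    std <- analytes$analyte[analytes$group == g & analytes$has_standard]
    unk <- analytes$analyte[analytes$group == g & !analytes$has_standard]
    true_rrf[unk] <- mean(true_rrf[std])
  }

  is_amount <- 50   # ng spiked per sample
  std <- analytes[analytes$has_standard, , drop = FALSE]
  standards <- data.frame(
    analyte = std$analyte, group = std$group, amount = 50,
    is_amount = is_amount, is_area = 1e6,
    stringsAsFactors = FALSE)
  standards$area <- true_rrf[standards$analyte] *
    (standards$amount / standards$is_amount) * standards$is_area

  recoveries <- do.call(rbind, lapply(meta$sample_id, function(sid)
    data.frame(sample_id = sid,
               surrogate = c("PCB117", "4p-159"),
               recovery = stats::runif(2, 0.75, 1.05),
               stringsAsFactors = FALSE)))

  sdlog_gc <- log(1.6)
  truth_conc <- list(); area_rows <- list(); atro <- list()
  for (k in seq_len(nrow(meta))) {
    sid <- meta$sample_id[k]
    mult <- .group_multiplier(config, meta$sex[k], meta$genotype[k])
    a_is <- 1e6
    area_rows[[length(area_rows) + 1L]] <- data.frame(
      sample_id = sid, analyte = "PFOS_IS", area = a_is,
      role = "internal_standard", stringsAsFactors = FALSE)
    for (j in seq_len(nrow(analytes))) {
      an <- analytes$analyte[j]
      conc <- analytes$median_conc[j] * mult *
        stats::rlnorm(1, 0, sdlog_gc)
      rec <- recoveries$recovery[recoveries$sample_id == sid &
                                   recoveries$surrogate ==
                                     analytes$surrogate[j]]
      area <- conc * meta$sample_mass[k] * rec * true_rrf[an] *
        a_is / is_amount
      ## mean-one log-normal noise: multiplicative error without bias
      if (noise_sdlog > 0)
        area <- area * stats::rlnorm(1, -noise_sdlog^2 / 2, noise_sdlog)
      area_rows[[length(area_rows) + 1L]] <- data.frame(
        sample_id = sid, analyte = an, area = area, role = "analyte",
        stringsAsFactors = FALSE)
      truth_conc[[length(truth_conc) + 1L]] <- data.frame(
        sample_id = sid, analyte = an, true_conc = conc,
        stringsAsFactors = FALSE)
    }
    grp <- paste(meta$sex[k], meta$genotype[k], sep = "_")
    ef <- config$ef_by_group[[grp]]
    tot <- stats::rlnorm(1, log(1e5), 0.3)
    atro[[length(atro) + 1L]] <- data.frame(
      sample_id = sid, group = grp, a_e1 = ef * tot,
      a_e2 = (1 - ef) * tot, true_ef = ef, stringsAsFactors = FALSE)
  }

  blanks <- list(method = abs(stats::rnorm(4, 0.5, 0.3)),
                 tissue = abs(stats::rnorm(4, 1.0, 0.5)))
  list(areas = do.call(rbind, area_rows), standards = standards,
       recoveries = recoveries,
       surrogate_map = analytes[, c("analyte", "surrogate")],
       analyte_groups = analytes[, c("analyte", "group", "has_standard")],
       meta = meta, atropisomers = do.call(rbind, atro), blanks = blanks,
       truth = list(concentrations = do.call(rbind, truth_conc),
                    rrf = true_rrf, recoveries = recoveries,
                    ef = config$ef_by_group),
       is_amount = is_amount)
}
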