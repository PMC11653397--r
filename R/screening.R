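## Semitargeted LC-HRMS screen: match the suspect list against per-sample
## centroided peak lists at a ppm tolerance, confirm hits by chlorine
## isotope pattern and (where available) PRM neutral-loss fragments,
## assign identification confidence, apply the majority-detection rule
## and normalize intensities to the PFOS volume corrector and wet mass.

#' Read / write centroided peak lists
#'
#' Peak lists are tab-separated with columns `sample_id`, `level`
#' (`MS1`/`MS2`), `precursor_mz` (NA for MS1), `rt_min`, `mz`,
#' `intensity`. `readPeakLists` accepts a single TSV or a directory of
#' TSVs and validates every row, reporting offending line numbers.
#'
#' @param path TSV file or directory of TSV files.
#' @return data.frame of peaks sorted by (sample_id, level, rt_min, mz).
#' @export
readPeakLists <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.tsv$", full.names = TRUE) else path
  if (!length(files)) stop("no peak-list files under ", path)
  out <- lapply(files, function(f) {
    if (!file.exists(f)) stop("peak-list file not found: ", f)
    if (file.size(f) == 0L || length(readLines(f, n = 1L)) == 0L) {
      warning("empty peak-list file: ", f)
      return(NULL)
    }
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    need <- c("sample_id", "level", "precursor_mz", "rt_min", "mz",
              "intensity")
    if (!all(need %in% names(tab)))
      stop("peak list ", f, " lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    bad <- which(!(tab$level %in% c("MS1", "MS2")) | tab$rt_min < 0 |
                   tab$mz <= 0 | tab$intensity < 0 | is.na(tab$mz))
    if (length(bad))
      stop("malformed peak rows in ", f, " at data line(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    tab[need]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), level = character(0),
                      precursor_mz = numeric(0), rt_min = numeric(0),
                      mz = numeric(0), intensity = numeric(0))
  out[order(out$sample_id, out$level, out$rt_min, out$mz), , drop = FALSE]
}

#' @rdname readPeakLists
#' @param peaks Peak data.frame to write.
#' @export
writePeakLists <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with columns `sample_id`, `sex` (M/F), `genotype` (WT/KO/KI),
#' `sample_mass` (g wet weight), `pfos_intensity` (volume-corrector
#' signal) and optionally `is_blank`.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
readSampleMeta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "genotype", "sample_mass", "pfos_intensity")
  if (!all(need %in% names(meta)))
    stop("metadata lacks columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (any(meta$sample_mass <= 0)) stop("sample_mass must be positive")
  if (any(meta$pfos_intensity <= 0)) stop("pfos_intensity must be positive")
  if (is.null(meta$is_blank)) meta$is_blank <- FALSE
  meta
}

#' Match suspect candidates against MS1 peak lists
#'
#' For every candidate x sample, MS1 peaks within `tolerance_ppm` of the
#' candidate's theoretical m/z are grouped into retention-time-contiguous
#' features (gap <= `rt_gap` min); the feature apex (most intense peak)
#' becomes one detection record. Candidates with no in-tolerance peak
#' produce no record. When two candidates claim the same apex peak both
#' records are kept and flagged ambiguous.
#'
#' @param peaks Peak data.frame (see [readPeakLists()]).
#' @param suspects A [SuspectList-class].
#' @param tolerance_ppm Mass tolerance in ppm (default 5).
#' @param rt_gap Maximum retention-time gap within one feature, minutes.
#' @return data.frame of unconfirmed detection records.
#' @export
matchCandidates <- function(peaks, suspects, tolerance_ppm = 5,
                            rt_gap = 0.2) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  cand <- candidates(suspects)
  ms1 <- peaks[peaks$level == "MS1", , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(cand))) {
    th <- cand$theoretical_mz[i]
    hit <- ms1[abs(ms1$mz - th) / th * 1e6 <= tolerance_ppm, , drop = FALSE]
    if (!nrow(hit)) next
    for (sid in unique(hit$sample_id)) {
      h <- hit[hit$sample_id == sid, , drop = FALSE]
      h <- h[order(h$rt_min), , drop = FALSE]
      feat <- cumsum(c(TRUE, diff(h$rt_min) > rt_gap))
      for (fg in unique(feat)) {
        hf <- h[feat == fg, , drop = FALSE]
        apex <- hf[which.max(hf$intensity), , drop = FALSE]
        recs[[length(recs) + 1L]] <- data.frame(
          class_id = cand$class_id[i], candidate = cand$name[i],
          neutral_formula = cand$neutral_formula[i],
          theoretical_mz = th, expected_losses = cand$expected_losses[i],
          sample_id = sid, rt = apex$rt_min, measured_mz = apex$mz,
          delta_ppm = ppmError(apex$mz, th),
          raw_intensity = apex$intensity, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) return(.empty_records())
  key <- paste(out$sample_id, out$rt, out$measured_mz)
  dup_keys <- unique(key[duplicated(key)])
  out$ambiguous <- key %in% dup_keys
  rownames(out) <- NULL
  out
}

.empty_records <- function() {
  data.frame(class_id = character(0), candidate = character(0),
             neutral_formula = character(0), theoretical_mz = numeric(0),
             expected_losses = character(0), sample_id = character(0),
             rt = numeric(0), measured_mz = numeric(0),
             delta_ppm = numeric(0), raw_intensity = numeric(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}

#' Confirm detection records by chlorine isotope pattern
#'
#' Scores the MS1 peaks at each record's feature apex against the
#' candidate's theoretical envelope with [patternScore()]. Records
#' scoring below `min_score` move to the audit set.
#'
#' @param records Records from [matchCandidates()].
#' @param peaks Peak data.frame.
#' @param tolerance_ppm Mass tolerance for envelope peak matching.
#' @param min_score Minimum cosine score to keep a record (default 0.95
#'   over the top four envelope peaks).
#' @param rt_tol Retention-time half-window (min) defining "at the apex".
#' @param top_n Number of most intense envelope peaks scored.
#' @return list with elements `confirmed` and `audit`, both record
#'   data.frames carrying an `isotope_score` column.
#' @export
confirmIsotopes <- function(records, peaks, tolerance_ppm = 5,
                            min_score = 0.95, rt_tol = 0.02, top_n = 4L) {
  if (!nrow(records)) {
    records$isotope_score <- numeric(0)
    return(list(confirmed = records, audit = records))
  }
  ms1 <- peaks[peaks$level == "MS1", , drop = FALSE]
  env_cache <- new.env(parent = emptyenv())
  records$isotope_score <- vapply(seq_len(nrow(records)), function(i) {
    f <- records$neutral_formula[i]
    if (is.null(env_cache[[f]]))
      env_cache[[f]] <- isotopeEnvelope(formula_parse(f))
    win <- ms1[ms1$sample_id == records$sample_id[i] &
                 abs(ms1$rt_min - records$rt[i]) <= rt_tol, , drop = FALSE]
    if (!nrow(win)) return(0)
    as.numeric(patternScore(env_cache[[f]], win[, c("mz", "intensity")],
                            tolerance_ppm = tolerance_ppm, top_n = top_n))
  }, numeric(1))
  keep <- records$isotope_score >= min_score
  list(confirmed = records[keep, , drop = FALSE],
       audit = records[!keep, , drop = FALSE])
}

#' Confirm diagnostic neutral-loss fragments from MS2 scans
#'
#' For each record, MS2 peaks whose precursor matches the candidate
#' within tolerance are searched for a fragment at
#' (theoretical m/z - loss mass) for every expected loss. Any confirmed
#' loss raises the identification confidence to level 2; otherwise (or
#' with no MS2 data at all) it stays level 3.
#'
#' @param records Record data.frame.
#' @param peaks Peak data.frame (MS2 rows carry `precursor_mz`).
#' @param tolerance_ppm Mass tolerance in ppm.
#' @return Records with columns `fragments_confirmed` (comma-separated
#'   confirmed loss labels) and `confidence_level` (2 or 3).
#' @export
confirmFragments <- function(records, peaks, tolerance_ppm = 5) {
  ms2 <- peaks[peaks$level == "MS2" & !is.na(peaks$precursor_mz), ,
               drop = FALSE]
  n <- nrow(records)
  records$fragments_confirmed <- character(n)
  records$confidence_level <- rep(3L, n)
  if (!n) return(records)
  for (i in seq_len(n)) {
    losses <- strsplit(records$expected_losses[i], ",")[[1]]
    losses <- losses[nzchar(losses)]
    if (!length(losses) || !nrow(ms2)) next
    th <- records$theoretical_mz[i]
    sc <- ms2[ms2$sample_id == records$sample_id[i] &
                abs(ms2$precursor_mz - th) / th * 1e6 <= tolerance_ppm, ,
              drop = FALSE]
    if (!nrow(sc)) next
    ok <- vapply(losses, function(lb) {
      fmz <- th - neutralLossMass(lb)
      any(abs(sc$mz - fmz) / fmz * 1e6 <= tolerance_ppm)
    }, logical(1))
    records$fragments_confirmed[i] <- paste(losses[ok], collapse = ",")
    if (any(ok)) records$confidence_level[i] <- 2L
  }
  records
}

#' PFOS- and mass-normalized relative abundance
#'
#' `relative_abundance = raw_intensity / (pfos_intensity * sample_mass)`;
#' records for samples missing from the metadata are dropped with a
#' warning.
#'
#' @param records Record data.frame.
#' @param meta Sample metadata (see [readSampleMeta()]).
#' @return Records with a `relative_abundance` column.
#' @export
relativeAbundance <- function(records, meta) {
  idx <- match(records$sample_id, meta$sample_id)
  if (anyNA(idx)) {
    warning("dropping records for samples without metadata: ",
            paste(unique(records$sample_id[is.na(idx)]), collapse = ", "))
    records <- records[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  records$relative_abundance <-
    records$raw_intensity / (meta$pfos_intensity[idx] * meta$sample_mass[idx])
  records
}

#' Majority-detection filter and screening report
#'
#' A candidate is retained only when detected in strictly more than half
#' of the study samples. The report adds per-candidate retention-time
#' statistics (mean RT and RRT relative to PFOS) and, when metadata are
#' supplied, per-group mean and SD of the relative abundance and a blank
#' flag (median blank relative abundance exceeding `blank_fraction` of
#' the study median).
#'
#' @param records Confirmed record data.frame.
#' @param n_samples Number of study (non-blank) samples screened.
#' @param meta Optional sample metadata (enables group summaries and
#'   blank flags).
#' @param pfos_rt Optional PFOS apex retention time (min) for RRT.
#' @param blank_fraction Blank-flag threshold (default 0.1).
#' @return data.frame, one row per candidate: `frequency`, `retained`,
#'   `mean_rt`, `rrt`, group summary columns, `blank_flagged`.
#' @export
frequencyFilter <- function(records, n_samples, meta = NULL, pfos_rt = NA,
                            blank_fraction = 0.1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(meta)) {
    blank_ids <- meta$sample_id[meta$is_blank]
    study_rec <- records[!(records$sample_id %in% blank_ids), , drop = FALSE]
    blank_rec <- records[records$sample_id %in% blank_ids, , drop = FALSE]
  } else {
    study_rec <- records
    blank_rec <- records[0, , drop = FALSE]
  }
  key <- unique(records[, c("class_id", "candidate", "neutral_formula",
                            "theoretical_mz")])
  if (!nrow(key)) key <- key[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(key)), function(i) {
    r <- study_rec[study_rec$candidate == key$candidate[i] &
                     study_rec$neutral_formula == key$neutral_formula[i], ,
                   drop = FALSE]
    freq <- length(unique(r$sample_id)) / n_samples
    out <- data.frame(key[i, , drop = FALSE],
                      frequency = freq, retained = freq > 0.5,
                      mean_rt = if (nrow(r)) mean(r$rt) else NA_real_,
                      rrt = if (nrow(r) && !is.na(pfos_rt))
                        mean(r$rt) / pfos_rt else NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(meta) && "relative_abundance" %in% names(r)) {
      grp <- paste(meta$sex, meta$genotype, sep = "_")[
        match(r$sample_id, meta$sample_id)]
      for (g in sort(unique(paste(meta$sex[!meta$is_blank],
                                  meta$genotype[!meta$is_blank],
                                  sep = "_")))) {
        v <- r$relative_abundance[grp == g]
        out[[paste0("mean_", g)]] <- if (length(v)) mean(v) else NA_real_
        out[[paste0("sd_", g)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      }
      b <- blank_rec[blank_rec$candidate == key$candidate[i] &
                       blank_rec$neutral_formula == key$neutral_formula[i], ,
                     drop = FALSE]
      med_study <- if (nrow(r)) stats::median(r$relative_abundance) else NA
      out$blank_flagged <- nrow(b) > 0 && !is.na(med_study) &&
        stats::median(b$relative_abundance) > blank_fraction * med_study
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(class_id = character(0), candidate = character(0),
                      neutral_formula = character(0),
                      theoretical_mz = numeric(0), frequency = numeric(0),
                      retained = logical(0), mean_rt = numeric(0),
                      rrt = numeric(0))
  rownames(out) <- NULL
  out[order(is.na(out$class_id), out$class_id), , drop = FALSE]
}

#' Run the full semitargeted screen
#'
#' match -> isotope confirmation -> fragment confirmation -> PFOS/mass
#' normalization -> majority filter, in one call.
#'
#' @param peaks Peak data.frame.
#' @param meta Sample metadata.
#' @param suspects A [SuspectList-class].
#' @param tolerance_ppm Mass tolerance (default 5 ppm).
#' @param min_isotope_score Isotope-score threshold (default 0.95).
#' @param rt_gap Feature retention-time gap (min).
#' @param frequency_on Count detection frequency on isotope-`"confirmed"`
#'   records (default) or on all `"matched"` records.
#' @return list: `detections` (confirmed records), `audit` (dropped),
#'   `report` (per-candidate summary, see [frequencyFilter()]).
#' @export
screenStudy <- function(peaks, meta, suspects, tolerance_ppm = 5,
                        min_isotope_score = 0.95, rt_gap = 0.2,
                        frequency_on = c("confirmed", "matched")) {
  frequency_on <- match.arg(frequency_on)
  matched <- matchCandidates(peaks, suspects, tolerance_ppm, rt_gap)
  conf <- confirmIsotopes(matched, peaks, tolerance_ppm,
                          min_score = min_isotope_score)
  det <- confirmFragments(conf$confirmed, peaks, tolerance_ppm)
  det <- relativeAbundance(det, meta)
  n_samples <- sum(!meta$is_blank)
  pfos_mz <- ionMz(formula_make(.PFOS_NEUTRAL))
  pfos_pk <- peaks[peaks$level == "MS1" &
                     abs(peaks$mz - pfos_mz) / pfos_mz * 1e6 <= tolerance_ppm, ,
                   drop = FALSE]
  pfos_rt <- if (nrow(pfos_pk)) stats::median(pfos_pk$rt_min) else NA_real_
  freq_input <- if (frequency_on == "confirmed") det else
    relativeAbundance(confirmFragments(matched, peaks, tolerance_ppm), meta)
  report <- frequencyFilter(freq_input, n_samples, meta = meta,
                            pfos_rt = pfos_rt)
  list(detections = det, audit = conf$audit, report = report)
}
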