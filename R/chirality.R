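## Enantiomeric fraction (EF) for atropisomer peak pairs, racemic QC
## against the racemic-standard EF, and a perpendicular-drop integrator
## for synthetic two-peak chromatograms. By the chiral-column elution
## order used here the second-eluting atropisomer (E2) is the aS
## configuration; that mapping is metadata and is not computed.

#' Enantiomeric fraction
#'
#' `EF = A_E1 / (A_E1 + A_E2)`: the first-eluting atropisomer's share of
#' the summed peak areas. 0.5 is racemic. Vectorised.
#'
#' @param a_e1,a_e2 Peak areas of the first- and second-eluting
#'   atropisomers (non-negative, not both zero).
#' @return EF in [0, 1].
#' @examples
#' computeEF(39, 61)  # 0.39
#' @export
computeEF <- function(a_e1, a_e2) {
  if (any(a_e1 < 0 | a_e2 < 0)) stop("peak areas must be non-negative")
  tot <- a_e1 + a_e2
  if (any(tot == 0)) stop("both atropisomer areas are zero")
  a_e1 / tot
}

#' Racemic check against the standard EF
#'
#' TRUE when |EF - reference| <= tol. Defaults encode the racemic
#' PCB95 standard (EF 0.498, SD 0.004, band 3 SD).
#'
#' @param ef EF value(s).
#' @param reference Racemic-standard EF.
#' @param tol Acceptance half-width.
#' @return Logical, TRUE when indistinguishable from racemic.
#' @export
racemicCheck <- function(ef, reference = 0.498, tol = 3 * 0.004) {
  if (reference < 0 || reference > 1) stop("reference EF must be in [0, 1]")
  abs(ef - reference) <= tol
}

#' EF table with group summary
#'
#' @param pairs data.frame `sample_id`, `a_e1`, `a_e2` and optionally a
#'   `group` column.
#' @return list: `samples` (per-sample EF + racemic flag) and `groups`
#'   (mean +/- SD per group, if groups given).
#' @export
efSummary <- function(pairs) {
  ef <- computeEF(pairs$a_e1, pairs$a_e2)
  samples <- data.frame(sample_id = pairs$sample_id, ef = ef,
                        racemic = racemicCheck(ef),
                        stringsAsFactors = FALSE)
  groups <- NULL
  if (!is.null(pairs$group)) {
    groups <- do.call(rbind, lapply(split(ef, pairs$group), function(v)
      data.frame(mean_ef = mean(v),
                 sd_ef = if (length(v) > 1) stats::sd(v) else NA_real_,
                 n = length(v))))
    groups <- data.frame(group = rownames(groups), groups,
                         row.names = NULL, stringsAsFactors = FALSE)
  }
  list(samples = samples, groups = groups)
}

#' Perpendicular-drop integration of a two-peak chromatogram
#'
#' Splits a sampled signal at the valley minimum between its two largest
#' maxima and integrates each side by the trapezoid rule. Intended for
#' generating synthetic atropisomer area pairs; real areas are inputs.
#'
#' @param time,signal Equal-length numeric vectors of a two-peak trace.
#' @return c(a_e1, a_e2) areas left and right of the valley.
#' @export
valleyDropAreas <- function(time, signal) {
  stopifnot(length(time) == length(signal), length(time) > 4)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
  pk <- which(diff(sign(diff(signal))) < 0) + 1L
  if (length(pk) < 2L) stop("fewer than two peaks in the trace")
  pk <- pk[order(-signal[pk])][1:2]
  pk <- sort(pk)
  valley <- pk[1] - 1L + which.min(signal[pk[1]:pk[2]])
  c(a_e1 = trapz(time[1:valley], signal[1:valley]),
    a_e2 = trapz(time[valley:length(time)], signal[valley:length(time)]))
}
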