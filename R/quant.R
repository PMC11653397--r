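## Targeted GC-MS/MS-style quantification: internal-standard calibration
## with relative response factors (RRF), surrogate-recovery correction,
## group-average RRFs for standards-free unknowns, and blank-based
## detection/quantification limits.

#' Relative response factors from a standard mixture
#'
#' `RRF = (A_analyte / A_IS) / (m_analyte / m_IS)` for each analyte of a
#' calibration standard.
#'
#' @param standards data.frame with columns `analyte`, `area`,
#'   `amount` (ng), `is_area`, `is_amount` (ng) and optionally `group`
#'   (transition group label used for averaging).
#' @return data.frame `analyte`, `group`, `rrf`.
#' @export
computeRRF <- function(standards) {
  need <- c("analyte", "area", "amount", "is_area", "is_amount")
  stopifnot(all(need %in% names(standards)))
  if (any(standards$is_area <= 0)) stop("internal-standard area must be > 0")
  if (any(standards$amount <= 0 | standards$is_amount <= 0))
    stop("standard amounts must be > 0")
  rrf <- (standards$area / standards$is_area) /
    (standards$amount / standards$is_amount)
  data.frame(analyte = standards$analyte,
             group = if (is.null(standards$group)) NA_character_
                     else standards$group,
             rrf = rrf, stringsAsFactors = FALSE)
}

#' Average RRF of a transition group
#'
#' @param rrf_table Output of [computeRRF()].
#' @param group Transition-group label.
#' @return Mean RRF of the group's standards.
#' @export
averageRRF <- function(rrf_table, group) {
  v <- rrf_table$rrf[!is.na(rrf_table$group) & rrf_table$group == group]
  if (!length(v)) stop("no calibration standards in transition group ", group)
  mean(v)
}

#' Internal-standard quantification with recovery correction
#'
#' `conc = (A_analyte / A_IS) / RRF * m_IS / sample_mass`, then divided by
#' the fractional surrogate recovery of the analyte's surrogate class.
#' Concentrations are in ng/g wet weight. Values below the analyte's LOQ
#' are flagged, not censored.
#'
#' @param areas data.frame with columns `sample_id`, `analyte`, `area`,
#'   `role` (`analyte` or `internal_standard`); exactly one
#'   internal-standard row per sample.
#' @param rrf_table [computeRRF()] output (or any data.frame with
#'   `analyte`, `rrf`).
#' @param is_amount Internal-standard amount spiked per sample, ng.
#' @param meta data.frame `sample_id`, `sample_mass` (g).
#' @param recoveries Optional data.frame `sample_id`, `surrogate`,
#'   `recovery` (fraction).
#' @param surrogate_map Optional data.frame `analyte`, `surrogate`
#'   assigning each analyte its recovery-correcting surrogate class.
#' @param limits Optional [blankLimits()] output for below-LOQ flagging.
#' @param recovery_cap Recoveries above this (or <= 0) are an error
#'   (default 1.5).
#' @return data.frame `sample_id`, `analyte`, `concentration` (ng/g),
#'   `recovery_corrected`, `below_loq`, `estimated`.
#' @export
quantifyAreas <- function(areas, rrf_table, is_amount, meta,
                          recoveries = NULL, surrogate_map = NULL,
                          limits = NULL, recovery_cap = 1.5) {
  stopifnot(all(c("sample_id", "analyte", "area", "role") %in% names(areas)))
  if (is_amount <= 0) stop("is_amount must be > 0")
  is_rows <- areas[areas$role == "internal_standard", , drop = FALSE]
  if (anyDuplicated(is_rows$sample_id) ||
      !all(unique(areas$sample_id) %in% is_rows$sample_id))
    stop("exactly one internal-standard row required per sample")
  if (any(is_rows$area <= 0)) stop("internal-standard area must be > 0")
  an <- areas[areas$role == "analyte", , drop = FALSE]
  a_is <- is_rows$area[match(an$sample_id, is_rows$sample_id)]
  rrf <- rrf_table$rrf[match(an$analyte, rrf_table$analyte)]
  if (anyNA(rrf))
    stop("no RRF for analyte(s): ",
         paste(unique(an$analyte[is.na(rrf)]), collapse = ", "))
  mass <- meta$sample_mass[match(an$sample_id, meta$sample_id)]
  if (anyNA(mass) || any(mass <= 0))
    stop("positive sample_mass required for every sample")
  conc <- (an$area / a_is) / rrf * is_amount / mass

  rec_corrected <- FALSE
  if (!is.null(recoveries)) {
    if (is.null(surrogate_map))
      stop("surrogate_map is required when recoveries are supplied")
    surr <- surrogate_map$surrogate[match(an$analyte, surrogate_map$analyte)]
    rk <- paste(an$sample_id, surr)
    rec <- recoveries$recovery[match(rk, paste(recoveries$sample_id,
                                               recoveries$surrogate))]
    if (anyNA(rec))
      stop("missing surrogate recovery for some sample/analyte pairs")
    if (any(rec <= 0 | rec > recovery_cap))
      stop("surrogate recovery outside (0, ", recovery_cap, "]")
    conc <- conc / rec
    rec_corrected <- TRUE
  }

  below <- rep(FALSE, length(conc))
  if (!is.null(limits)) {
    loq <- limits$loq[match(an$analyte, limits$analyte)]
    below <- !is.na(loq) & conc < loq
  }
  data.frame(sample_id = an$sample_id, analyte = an$analyte,
             concentration = conc, recovery_corrected = rec_corrected,
             below_loq = below, estimated = FALSE,
             stringsAsFactors = FALSE)
}

#' Estimate an unknown metabolite with a group-average RRF
#'
#' Unknown metabolites without authentic standards are quantified with
#' the mean RRF of their transition group's calibrated standards; results
#' are flagged `estimated`.
#'
#' @param areas,is_amount,meta,recoveries,surrogate_map,limits As in
#'   [quantifyAreas()]; `areas` holds the unknown's rows.
#' @param rrf_table [computeRRF()] output with a `group` column.
#' @param transition_group Transition-group label of the unknown.
#' @return As [quantifyAreas()], with `estimated = TRUE`.
#' @export
estimateUnknown <- function(areas, rrf_table, transition_group, is_amount,
                            meta, recoveries = NULL, surrogate_map = NULL,
                            limits = NULL) {
  g_rrf <- averageRRF(rrf_table, transition_group)
  an <- unique(areas$analyte[areas$role == "analyte"])
  res <- quantifyAreas(areas,
                       data.frame(analyte = an, rrf = g_rrf),
                       is_amount, meta, recoveries, surrogate_map, limits)
  res$estimated <- TRUE
  res
}

#' Blank-based detection and quantification limits
#'
#' `MDL = mean(method blanks) + 3 * SD`;
#' `LOQ = mean(tissue blanks) + 10 * SD`. With a single blank the SD term
#' is zero; fewer than 3 blanks triggers a warning.
#'
#' @param method_blanks Numeric blank concentrations for the MDL.
#' @param tissue_blanks Numeric matrix-matched blank concentrations for
#'   the LOQ (defaults to `method_blanks`).
#' @param analyte Analyte label carried into the output.
#' @return data.frame `analyte`, `mdl`, `loq` (ng/g).
#' @export
blankLimits <- function(method_blanks, tissue_blanks = method_blanks,
                        analyte = NA_character_) {
  if (!length(method_blanks) || !length(tissue_blanks))
    stop("at least one blank measurement is required")
  if (length(method_blanks) < 3L || length(tissue_blanks) < 3L)
    warning("fewer than 3 blanks; limit estimates will be unstable")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  mdl <- mean(method_blanks) + 3 * sd0(method_blanks)
  loq <- mean(tissue_blanks) + 10 * sd0(tissue_blanks)
  if (loq < mdl) warning("LOQ fell below MDL; check blank sets")
  data.frame(analyte = analyte, mdl = mdl, loq = loq,
             stringsAsFactors = FALSE)
}

#' Molar summary of parent and hydroxylated metabolites
#'
#' Converts ng/g concentrations to molar amounts, sums the hydroxylated
#' metabolites, and reports the molar percentage of the parent compound
#' and of the summed metabolites (normalized over the two, summing to
#' 100) plus the metabolite-to-parent molar fold ratio per sample.
#'
#' @param results [quantifyAreas()]-style data.frame.
#' @param masses Named numeric vector analyte -> molecular mass (g/mol).
#' @param parent Analyte label of the parent compound.
#' @return data.frame per sample: `parent_conc`, `sum_oh_conc` (ng/g),
#'   `parent_molar_pct`, `oh_molar_pct`, `fold_ratio`.
#' @export
molarSummary <- function(results, masses, parent = "PCB95") {
  if (!parent %in% results$analyte) stop("parent analyte not in results")
  mm <- masses[results$analyte]
  if (anyNA(mm))
    stop("missing molecular mass for: ",
         paste(unique(results$analyte[is.na(mm)]), collapse = ", "))
  moles <- results$concentration / mm   # nmol/g
  rows <- lapply(unique(results$sample_id), function(sid) {
    sel <- results$sample_id == sid
    is_par <- sel & results$analyte == parent
    is_oh <- sel & results$analyte != parent
    n_par <- sum(moles[is_par])
    n_oh <- sum(moles[is_oh])
    tot <- n_par + n_oh
    data.frame(sample_id = sid,
               parent_conc = sum(results$concentration[is_par]),
               sum_oh_conc = sum(results$concentration[is_oh]),
               parent_molar_pct = if (tot > 0) n_par / tot * 100 else NA_real_,
               oh_molar_pct = if (tot > 0) n_oh / tot * 100 else NA_real_,
               fold_ratio = if (n_par > 0) n_oh / n_par else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
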