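## Isotope-envelope computation: exact multinomial fine structure by
## repeated convolution, then aggregation to nominal (unit-Da) peaks.
## Polychlorinated ions carry the diagnostic M/M+2/M+4 pattern used to
## confirm suspect hits.

.point_mass <- function() new("IsotopeDistribution", mass = 0, abundance = 1)

## merge entries closer than `merge_tol` Da (abundance-weighted mass),
## drop entries below `prune`, optionally renormalize.
.tidy_dist <- function(mass, abundance, prune = 0, merge_tol = 1e-6,
                       renormalize = FALSE) {
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  grp <- cumsum(c(TRUE, diff(mass) > merge_tol))
  m <- as.numeric(tapply(mass * abundance, grp, sum) /
                    tapply(abundance, grp, sum))
  a <- as.numeric(tapply(abundance, grp, sum))
  keep <- a > prune
  m <- m[keep]; a <- a[keep]
  if (renormalize) a <- a / sum(a)
  new("IsotopeDistribution", mass = m, abundance = a)
}

#' Convolve two isotope distributions
#'
#' All pairwise mass sums with abundance products, merged within 1e-6 Da,
#' pruned below `prune` and (optionally) renormalized. Commutative and
#' associative up to the pruning tolerance.
#'
#' @param a,b [IsotopeDistribution-class] objects.
#' @param prune Abundance threshold below which entries are dropped.
#' @param renormalize Rescale abundances to sum to 1 after pruning
#'   (default TRUE; envelope construction keeps the pruning loss visible
#'   by passing FALSE).
#' @return An [IsotopeDistribution-class].
#' @export
convolveDist <- function(a, b, prune = 1e-6, renormalize = TRUE) {
  stopifnot(is(a, "IsotopeDistribution"), is(b, "IsotopeDistribution"))
  mass <- outer(a@mass, b@mass, "+")
  ab <- outer(a@abundance, b@abundance)
  .tidy_dist(as.numeric(mass), as.numeric(ab), prune = prune,
             renormalize = renormalize)
}

#' Isotope distribution of n atoms of one element
#'
#' Exact multinomial distribution over the isotopologue compositions of
#' `n` atoms, from the pinned isotope table. `n = 0` gives the identity
#' point mass at 0 Da.
#'
#' @param element Element symbol.
#' @param n Atom count (>= 0).
#' @param prune Abundance pruning threshold passed to the convolution.
#' @return An [IsotopeDistribution-class].
#' @examples
#' elementDistribution("Cl", 1)  # 35Cl : 37Cl = 0.7576 : 0.2424
#' @export
elementDistribution <- function(element, n, prune = 1e-12) {
  iso <- .ISOTOPES[[element]]
  if (is.null(iso)) stop("no isotope table for element: ", element)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  single <- new("IsotopeDistribution", mass = iso$mass,
                abundance = iso$abundance)
  out <- .point_mass()
  ## binary exponentiation keeps the entry count manageable for large n
  base <- single
  while (n > 0L) {
    if (n %% 2L == 1L)
      out <- convolveDist(out, base, prune = prune, renormalize = FALSE)
    n <- n %/% 2L
    if (n > 0L) base <- convolveDist(base, base, prune = prune,
                                     renormalize = FALSE)
  }
  out
}

#' Fine-structure isotope distribution of a formula
#'
#' @param formula An [ElementalFormula-class].
#' @param prune Abundance pruning threshold.
#' @return An [IsotopeDistribution-class] over exact isotopologue masses.
#' @export
formulaDistribution <- function(formula, prune = 1e-12) {
  stopifnot(is(formula, "ElementalFormula"))
  cts <- formula@counts
  out <- .point_mass()
  for (el in names(cts))
    out <- convolveDist(out, elementDistribution(el, cts[[el]], prune),
                        prune = prune, renormalize = FALSE)
  out
}

#' Nominal isotope envelope of a deprotonated ion
#'
#' Convolves the element distributions of the ion formula, aggregates the
#' fine structure into unit-Da bins at integer offsets from the
#' monoisotopic peak, and scales the base (most intense) peak to 100.
#' For a pentachlorinated ion the leading M : M+2 : M+4 : M+6 peaks show
#' the characteristic chlorine pattern (about 62 : 100 : 65 : 21).
#'
#' @param neutral Neutral [ElementalFormula-class] of the candidate.
#' @param charge Ion charge (negative; default -1).
#' @param prune Fine-structure pruning threshold (abundance fraction).
#' @return data.frame with columns `offset` (integer Da from the
#'   monoisotopic peak), `mz` (abundance-weighted exact m/z of the bin),
#'   `abundance` (fraction of all isotopologues) and `rel_intensity`
#'   (base peak = 100).
#' @examples
#' env <- isotopeEnvelope(formula_parse("C12H5Cl5O"))
#' env[env$offset %in% c(0, 2, 4, 6), ]
#' @export
isotopeEnvelope <- function(neutral, charge = -1L, prune = 1e-6) {
  ion <- ionFormula(neutral, charge)
  z <- abs(as.integer(charge))
  fine <- formulaDistribution(ion, prune = prune)
  mono <- fine@mass[1]
  offset <- as.integer(round(fine@mass - mono))
  mz <- (fine@mass + z * .ELECTRON_MASS) / z
  agg_ab <- tapply(fine@abundance, offset, sum)
  agg_mz <- tapply(mz * fine@abundance, offset, sum) / agg_ab
  out <- data.frame(offset = as.integer(names(agg_ab)),
                    mz = as.numeric(agg_mz),
                    abundance = as.numeric(agg_ab))
  out <- out[order(out$offset), , drop = FALSE]
  out$rel_intensity <- out$abundance / max(out$abundance) * 100
  rownames(out) <- NULL
  out
}

#' Score an observed peak cluster against a theoretical envelope
#'
#' Matches observed centroids to the envelope's per-bin m/z within a ppm
#' tolerance (an unmatched theoretical peak contributes zero intensity)
#' and returns the cosine between the matched observed intensities and
#' the theoretical pattern: 1 for perfectly proportional patterns, 0 for
#' orthogonal ones. If no observed peak matches the monoisotopic
#' position the score is 0 and the result carries
#' `attr(., "monoisotopic_missing") = TRUE`.
#'
#' @param theoretical Envelope data.frame from [isotopeEnvelope()].
#' @param observed Two-column matrix or data.frame of (mz, intensity).
#' @param tolerance_ppm Match tolerance in ppm.
#' @param top_n Restrict scoring to the `top_n` most intense theoretical
#'   peaks (default 4, the visually diagnostic chlorine peaks); `NULL`
#'   scores the full envelope.
#' @return Score in [0, 1].
#' @export
patternScore <- function(theoretical, observed, tolerance_ppm = 5,
                         top_n = 4L) {
  if (NROW(observed) == 0L) stop("observed peak list is empty")
  obs_mz <- observed[[1]]
  obs_int <- observed[[2]]
  th <- theoretical
  if (!is.null(top_n) && nrow(th) > top_n)
    th <- th[order(-th$rel_intensity)[seq_len(top_n)], , drop = FALSE]
  th <- th[order(th$offset), , drop = FALSE]
  matched <- vapply(th$mz, function(m) {
    hit <- abs(ppmError(obs_mz, m)) <= tolerance_ppm
    if (any(hit)) max(obs_int[hit]) else 0
  }, numeric(1))
  if (0L %in% th$offset && matched[th$offset == 0L] == 0) {
    out <- 0
    attr(out, "monoisotopic_missing") <- TRUE
    return(out)
  }
  t_vec <- th$rel_intensity
  denom <- sqrt(sum(matched^2)) * sqrt(sum(t_vec^2))
  if (denom == 0) return(0)
  sum(matched * t_vec) / denom
}

#' Export an envelope as CSV
#'
#' @param envelope data.frame from [isotopeEnvelope()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeEnvelope <- function(envelope, path) {
  utils::write.csv(envelope[, c("offset", "mz", "rel_intensity")], path,
                   row.names = FALSE)
  invisible(path)
}
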