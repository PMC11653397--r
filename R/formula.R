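## Formula arithmetic and exact-mass computation.

#' Build an elemental formula
#'
#' @param ... Element counts as named arguments (`C = 12, H = 5, Cl = 5`),
#'   or a single named vector.
#' @return An [ElementalFormula-class].
#' @examples
#' formula_make(C = 12, H = 5, Cl = 5)   # PCB95
#' @export
formula_make <- function(...) {
  args <- list(...)
  if (length(args) == 1L && length(args[[1]]) > 1L && !is.null(names(args[[1]])))
    cts <- args[[1]]
  else
    cts <- unlist(args)
  if (is.null(cts)) cts <- integer(0)
  cts <- cts[cts != 0]
  storage.mode(cts) <- "integer"
  new("ElementalFormula", counts = cts)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as `"C12H5Cl5O"`; counts default to 1.
#'
#' @param x A formula string.
#' @return An [ElementalFormula-class].
#' @examples
#' formula_parse("C12H4Cl5O")
#' @export
formula_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(formula_make())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula string: ", x)
  el <- sub("[0-9]+$", "", toks)
  n  <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  cts <- tapply(n, el, sum)
  formula_make(stats::setNames(as.integer(cts), names(cts)))
}

#' Render a formula in Hill notation
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (all elements alphabetical if there is no carbon).
#'
#' @param x An [ElementalFormula-class].
#' @return A character string; `""` for the empty formula.
#' @export
formulaToString <- function(x) {
  cts <- x@counts
  if (!length(cts)) return("")
  el <- names(cts)
  if ("C" %in% el) {
    ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  } else ord <- sort(el)
  paste0(vapply(ord, function(e) {
    n <- cts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @describeIn formula_make Element-wise sum of two formulas.
#' @param e1,e2 [ElementalFormula-class] objects.
#' @export
setMethod("+", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  all_el <- union(names(e1@counts), names(e2@counts))
  cts <- vapply(all_el, function(e) {
    sum(e1@counts[e], e2@counts[e], na.rm = TRUE)
  }, numeric(1))
  formula_make(stats::setNames(as.integer(cts), all_el))
})

#' @describeIn formula_make Element-wise difference; errors if any count
#'   would go negative.
#' @export
setMethod("-", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  all_el <- union(names(e1@counts), names(e2@counts))
  cts <- vapply(all_el, function(e) {
    sum(e1@counts[e], na.rm = TRUE) - sum(e2@counts[e], na.rm = TRUE)
  }, numeric(1))
  if (any(cts < 0))
    stop("subtraction would give a negative count for element ",
         paste(all_el[cts < 0], collapse = ", "))
  formula_make(stats::setNames(as.integer(cts), all_el))
})

#' @describeIn formula_make Count-wise equality.
#' @export
setMethod("==", signature("ElementalFormula", "ElementalFormula"),
          function(e1, e2) {
  identical(e1@counts[order(names(e1@counts))],
            e2@counts[order(names(e2@counts))])
})

#' Monoisotopic mass of a formula
#'
#' The exact mass of the isotopologue made entirely of each element's
#' principal (most abundant) isotope, summed from a pinned atomic-mass
#' table. The empty formula has mass zero.
#'
#' @param formula An [ElementalFormula-class].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(formula_parse("C12H5Cl5"))  # PCB95, 323.88339 Da
#' @export
monoisotopicMass <- function(formula) {
  stopifnot(is(formula, "ElementalFormula"))
  cts <- formula@counts
  if (!length(cts)) return(0)
  unknown <- setdiff(names(cts), names(.MONO_MASS))
  if (length(unknown))
    stop("no tabulated isotope mass for element(s): ",
         paste(unknown, collapse = ", "))
  sum(cts * .MONO_MASS[names(cts)])
}

#' Theoretical m/z of a deprotonated (or multiply deprotonated) ion
#'
#' For a negative ion formed by removing `|charge|` protons from the
#' neutral molecule, m/z = (M(neutral - H.|z|) + |z|.m_e) / |z|: each
#' negative charge retains one extra electron, whose mass (0.00054858 Da)
#' is required for five-decimal agreement with reference anion masses.
#'
#' @param neutral Neutral-molecule [ElementalFormula-class].
#' @param charge Signed integer charge; the study uses -1 throughout.
#' @return m/z in Da (Th).
#' @examples
#' ionMz(formula_parse("C12H5Cl5O"), -1)  # 338.87103
#' @export
ionMz <- function(neutral, charge = -1L) {
  stopifnot(is(neutral, "ElementalFormula"))
  charge <- as.integer(charge)
  if (is.na(charge) || charge == 0L) stop("charge must be a non-zero integer")
  if (charge > 0L)
    stop("only deprotonated negative ions are modeled (charge < 0)")
  z <- abs(charge)
  nH <- if ("H" %in% names(neutral@counts)) neutral@counts[["H"]] else 0L
  if (nH < z)
    stop("cannot remove ", z, " H from ", formulaToString(neutral))
  ion <- neutral - formula_make(H = z)
  (monoisotopicMass(ion) + z * .ELECTRON_MASS) / z
}

#' Ion formula after deprotonation
#'
#' @param neutral Neutral [ElementalFormula-class].
#' @param charge Signed integer charge (negative).
#' @return The ion's [ElementalFormula-class] (neutral minus `|charge|` H).
#' @export
ionFormula <- function(neutral, charge = -1L) {
  z <- abs(as.integer(charge))
  if (z == 0L) stop("charge must be non-zero")
  neutral - formula_make(H = z)
}

#' Relative mass error in ppm
#'
#' `(measured - theoretical) / theoretical * 1e6`, signed.
#'
#' @param measured,theoretical m/z values in Da; `theoretical` must be > 0.
#' @return Mass error in ppm (vectorised).
#' @export
ppmError <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (measured - theoretical) / theoretical * 1e6
}
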