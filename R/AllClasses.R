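#' @import methods
NULL

#' Elemental formula
#'
#' An elemental composition: a named count of atoms per element symbol.
#' Counts are non-negative integers; elements with count zero are dropped,
#' so equality is count-wise. Arithmetic (`+`, `-`) is element-wise and
#' errors rather than produce a negative count.
#'
#' @slot counts Named integer vector, element symbol to atom count.
#' @seealso [formula_parse()], [monoisotopicMass()], [ionMz()]
#' @exportClass ElementalFormula
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cts <- object@counts
  if (length(cts) && is.null(names(cts)))
    return("counts must be named by element symbol")
  if (any(is.na(cts)) || any(cts < 0L))
    return("element counts must be non-negative integers")
  if (any(cts == 0L))
    return("zero-count elements must be dropped, not stored")
  if (anyDuplicated(names(cts)))
    return("duplicated element symbols")
  TRUE
})

#' Biotransformation rule
#'
#' One metabolic transformation expressed as a signed element-count delta,
#' with an applicability constraint and a cap on how often it may fire
#' along one transformation chain. The built-in rule set
#' ([defaultRules()]) covers P450 oxidation (OX, +O), phenol O-sulfation
#' (SULF-O, +SO3), ring C-sulfonation (SULFON-C, +SO3), catechol
#' O-methylation (METH, +CH2) and reductive dechlorination
#' (DECHLOR, -Cl +H).
#'
#' @slot name Rule label.
#' @slot delta Named numeric vector of signed element-count changes.
#' @slot constraint Function of (formula, applied-rule-name-vector)
#'   returning TRUE when the rule may fire.
#' @slot maxApplications Maximum times the rule may fire in one chain.
#' @exportClass BiotransformationRule
setClass("BiotransformationRule",
         representation(name = "character", delta = "numeric",
                        constraint = "function", maxApplications = "numeric"))

setValidity("BiotransformationRule", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (is.null(names(object@delta)) || any(object@delta == 0))
    return("delta must be a named vector of non-zero signed counts")
  if (object@maxApplications < 1)
    return("maxApplications must be >= 1")
  TRUE
})

#' Isotope distribution
#'
#' A fine-structure isotope distribution: exact isotopologue masses (Da)
#' with abundance fractions. Masses are strictly increasing after
#' aggregation and abundances sum to one (before pruning).
#'
#' @slot mass Numeric vector of exact masses in Da (strictly increasing).
#' @slot abundance Numeric vector of abundance fractions.
#' @exportClass IsotopeDistribution
setClass("IsotopeDistribution",
         representation(mass = "numeric", abundance = "numeric"))

setValidity("IsotopeDistribution", function(object) {
  if (length(object@mass) != length(object@abundance))
    return("mass and abundance lengths differ")
  if (length(object@mass) == 0L)
    return("distribution must have at least one entry")
  if (any(object@abundance < 0))
    return("abundances must be non-negative")
  if (is.unsorted(object@mass, strictly = TRUE))
    return("masses must be strictly increasing")
  TRUE
})

#' Suspect candidate list
#'
#' The suspect-screening list produced by [enumerateSuspects()]: one row
#' per candidate metabolite (a neutral formula plus a metabolite class;
#' positional isomers are not distinguished). Carries the deprotonated-ion
#' formula, theoretical m/z, expected diagnostic neutral losses, and the
#' rule provenance that generated the candidate from the parent compound.
#'
#' @slot candidates data.frame with columns class_id, name,
#'   neutral_formula, ion_formula, theoretical_mz, expected_losses
#'   (comma-separated labels), provenance (comma-separated rule names).
#' @slot parent The parent [ElementalFormula-class].
#' @exportClass SuspectList
setClass("SuspectList",
         representation(candidates = "data.frame", parent = "ElementalFormula"))

setValidity("SuspectList", function(object) {
  need <- c("class_id", "name", "neutral_formula", "ion_formula",
            "theoretical_mz", "expected_losses", "provenance")
  if (!all(need %in% names(object@candidates)))
    return(paste("candidates must have columns:", paste(need, collapse = ", ")))
  if (any(object@candidates$theoretical_mz <= 0))
    return("theoretical_mz must be positive")
  key <- paste(object@candidates$neutral_formula, object@candidates$class_id)
  if (anyDuplicated(key))
    return("duplicated (formula, class) pair")
  TRUE
})

#' @describeIn ElementalFormula-class Display a formula in Hill notation.
#' @param object An object.
#' @export
setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formulaToString(object), "\n")
})

#' @describeIn BiotransformationRule-class Display a rule.
#' @export
setMethod("show", "BiotransformationRule", function(object) {
  d <- object@delta
  cat(sprintf("BiotransformationRule %s: %s (max %d per chain)\n",
              object@name,
              paste(sprintf("%+d%s", as.integer(d), names(d)), collapse = " "),
              as.integer(object@maxApplications)))
})

#' @describeIn IsotopeDistribution-class Display the first entries.
#' @export
setMethod("show", "IsotopeDistribution", function(object) {
  n <- length(object@mass)
  cat(sprintf("IsotopeDistribution with %d isotopologue peak%s\n",
              n, if (n == 1L) "" else "s"))
  k <- min(n, 6L)
  print(data.frame(mass = round(object@mass[seq_len(k)], 6),
                   abundance = signif(object@abundance[seq_len(k)], 6)))
  if (n > k) cat("...\n")
})

#' @describeIn SuspectList-class Display a summary of the candidates.
#' @export
setMethod("show", "SuspectList", function(object) {
  cat(sprintf("SuspectList: %d candidates from parent %s\n",
              nrow(object@candidates), formulaToString(object@parent)))
  cls <- object@candidates$class_id
  cat(sprintf("  %d assigned to named metabolite classes: %s\n",
              sum(!is.na(cls)),
              paste(sort(unique(cls[!is.na(cls)])), collapse = ", ")))
})

#' @describeIn SuspectList-class Number of candidates.
#' @param x A SuspectList.
#' @export
setMethod("length", "SuspectList", function(x) nrow(x@candidates))

#' Candidate table of a SuspectList
#'
#' @param x A [SuspectList-class].
#' @param ... Ignored.
#' @return data.frame of candidates (see the class documentation).
#' @export
candidates <- function(x, ...) {
  stopifnot(is(x, "SuspectList"))
  x@candidates
}
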