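## Biotransformation rule engine: the suspect-list generator.
##
## Candidates are formula + metabolite class; positional isomers are not
## distinguished (reversed-phase LC cannot separate them reliably, and
## several hydroxylated isomers coelute). Methylation is restricted to
## chains with at least two prior oxidations because catechol
## O-methyltransferase acts on vicinal diols, which formula arithmetic
## alone cannot see -- the provenance carries that information.

.conjugation_rules <- c("SULF-O", "SULFON-C", "METH")

#' Built-in biotransformation rule set
#'
#' Rules for the mammalian PCB95 metabolic pathway: `OX` (P450
#' hydroxylation, +O), `SULF-O` (O-sulfation of a phenol, +SO3), `SULFON-C`
#' (ring C-sulfonation via the mercapturic-acid pathway, +SO3), `METH`
#' (catechol O-methylation, +CH2) and `DECHLOR` (gut-microbial reductive
#' dechlorination, -Cl +H). Default per-chain caps (`OX` 3, conjugations 1
#' each and mutually exclusive, `DECHLOR` 2) cover the detectable class
#' set without combinatorial blow-up.
#'
#' @param ox_max,dechlor_max Per-chain caps for oxidation and
#'   dechlorination.
#' @return Named list of [BiotransformationRule-class] objects.
#' @export
defaultRules <- function(ox_max = 3L, dechlor_max = 2L) {
  no_conj <- function(formula, provenance)
    !any(provenance %in% .conjugation_rules)
  list(
    ## conjugation (phase II) is terminal: no further phase-I steps fire
    ## on a conjugate, which keeps the closure free of formula duplicates
    OX = new("BiotransformationRule", name = "OX", delta = c(O = 1),
             constraint = no_conj,
             maxApplications = ox_max),
    `SULF-O` = new("BiotransformationRule", name = "SULF-O",
                   delta = c(S = 1, O = 3),
                   constraint = function(formula, provenance)
                     sum(provenance == "OX") >= 1L &&
                       no_conj(formula, provenance),
                   maxApplications = 1),
    ## ring sulfonation acts on the unoxidized biphenyl core; allowing it
    ## after OX would only duplicate the O-sulfate formulas
    `SULFON-C` = new("BiotransformationRule", name = "SULFON-C",
                     delta = c(S = 1, O = 3),
                     constraint = function(formula, provenance)
                       sum(provenance == "OX") == 0L &&
                         no_conj(formula, provenance),
                     maxApplications = 1),
    METH = new("BiotransformationRule", name = "METH",
               delta = c(C = 1, H = 2),
               constraint = function(formula, provenance)
                 sum(provenance == "OX") >= 2L &&
                   no_conj(formula, provenance),
               maxApplications = 1),
    DECHLOR = new("BiotransformationRule", name = "DECHLOR",
                  delta = c(Cl = -1, H = 1),
                  constraint = function(formula, provenance) {
                    ncl <- formula@counts["Cl"]
                    !is.na(ncl) && ncl >= 1L &&
                      !any(provenance %in% .conjugation_rules)
                  },
                  maxApplications = dechlor_max)
  )
}

#' Apply one biotransformation rule to a formula
#'
#' Checks the rule's constraint against the formula and the chain's prior
#' provenance, then adds the signed element delta. Errors (naming rule
#' and formula) if the constraint fails or a count would go negative.
#'
#' @param formula An [ElementalFormula-class].
#' @param rule A [BiotransformationRule-class].
#' @param provenance Character vector of rule names already applied in
#'   this chain (used by provenance-dependent constraints).
#' @return The transformed [ElementalFormula-class].
#' @examples
#' applyRule(formula_parse("C12H5Cl5"), defaultRules()$OX)
#' @export
applyRule <- function(formula, rule, provenance = character()) {
  stopifnot(is(formula, "ElementalFormula"), is(rule, "BiotransformationRule"))
  if (sum(provenance == rule@name) >= rule@maxApplications)
    stop("rule ", rule@name, " exceeds its per-chain cap (",
         rule@maxApplications, ") on ", formulaToString(formula))
  if (!isTRUE(rule@constraint(formula, provenance)))
    stop("constraint of rule ", rule@name, " not satisfied on ",
         formulaToString(formula))
  d <- rule@delta
  all_el <- union(names(formula@counts), names(d))
  cts <- vapply(all_el, function(e)
    sum(formula@counts[e], na.rm = TRUE) + sum(d[e], na.rm = TRUE),
    numeric(1))
  if (any(cts < 0))
    stop("rule ", rule@name, " would give a negative ",
         paste(all_el[cts < 0], collapse = ","), " count on ",
         formulaToString(formula))
  formula_make(stats::setNames(as.integer(cts), all_el))
}

## Map a provenance signature to the metabolite-class catalogue.
## Returns list(class_id, name); class_id is NA for pathway intermediates
## that are generated but not part of the named class set.
.classify_candidate <- function(formula, provenance) {
  nOX <- sum(provenance == "OX")
  nDE <- sum(provenance == "DECHLOR")
  conj <- intersect(.conjugation_rules, provenance)
  conj <- if (length(conj)) conj[1] else "none"
  ncl <- sum(formula@counts["Cl"], na.rm = TRUE)
  free_oh <- nOX - (conj == "SULF-O") - (conj == "METH")

  core <- if (ncl == 5L) "PCB95"
          else paste0(c("", "mono", "di", "tri", "tetra")[ncl + 1L], "-CB")
  oh_prefix <- c("", "OH-", "diOH-", "triOH-")[max(free_oh, 0L) + 1L]
  name <- paste0(if (conj == "METH") "MeO-" else "", oh_prefix, core,
                 switch(conj, `SULF-O` = " sulfate",
                        `SULFON-C` = " sulfonate", ""))
  if (!length(provenance)) name <- core

  key <- paste(nOX, conj, nDE)
  class_id <- switch(key,
    "1 none 0"   = "1.1",  # OH-PCB95
    "1 SULF-O 0" = "1.2",  # PCB95 sulfate
    "2 SULF-O 0" = "2",    # OH-PCB95 sulfate
    "2 METH 0"   = "3",    # MeO-OH-PCB95
    "3 METH 0"   = "4",    # MeO-diOH-PCB95
    "0 SULFON-C 0" = "5",  # PCB95 sulfonate
    "1 none 2"   = "6",    # OH-tri-CB
    "1 none 1"   = "7",    # OH-tetra-CB
    "2 none 2"   = "8",    # diOH-tri-CB
    NA_character_)
  list(class_id = class_id, name = name, free_oh = free_oh, conj = conj)
}

#' Diagnostic neutral losses expected for a candidate
#'
#' O-sulfates fragment by SO3 loss, methylated catechols by CH3 radical
#' loss, chlorinated phenols by HCl loss; ring sulfonates and the parent
#' give no diagnostic loss. Loss masses are computed from the atomic-mass
#' table, never hard-coded.
#'
#' @param provenance Character vector of applied rule names.
#' @param formula The candidate's neutral [ElementalFormula-class].
#' @return data.frame with columns `label` and `mass` (Da); zero rows when
#'   no diagnostic loss is expected.
#' @export
expectedLosses <- function(provenance, formula) {
  cls <- .classify_candidate(formula, provenance)
  ncl <- sum(formula@counts["Cl"], na.rm = TRUE)
  if (cls$conj == "SULF-O")
    return(data.frame(label = "SO3",
                      mass = monoisotopicMass(formula_make(S = 1, O = 3))))
  if (cls$conj == "METH")
    return(data.frame(label = "CH3",
                      mass = monoisotopicMass(formula_make(C = 1, H = 3))))
  if (cls$conj == "none" && cls$free_oh >= 1L && ncl >= 1L)
    return(data.frame(label = "HCl",
                      mass = monoisotopicMass(formula_make(H = 1, Cl = 1))))
  data.frame(label = character(0), mass = numeric(0))
}

#' Neutral-loss mass by label
#'
#' @param label One of `"HCl"`, `"SO3"`, `"CH3"`.
#' @return Loss mass in Da.
#' @export
neutralLossMass <- function(label) {
  comp <- switch(label,
                 HCl = formula_make(H = 1, Cl = 1),
                 SO3 = formula_make(S = 1, O = 3),
                 CH3 = formula_make(C = 1, H = 3),
                 stop("unknown neutral-loss label: ", label))
  monoisotopicMass(comp)
}

#' Enumerate suspect metabolite candidates
#'
#' Breadth-first closure of the rule set over the parent formula, subject
#' to each rule's constraint and per-chain cap and an overall chain-length
#' cap. Candidates are deduplicated by (neutral formula, class); the
#' result is independent of rule application order. With the default
#' rules and parent PCB95 the list covers all named metabolite classes
#' 1.1 through 8.
#'
#' @param parent Parent [ElementalFormula-class] (default PCB95,
#'   C12H5Cl5).
#' @param rules List of [BiotransformationRule-class] (default
#'   [defaultRules()]).
#' @param max_chain Maximum number of rule applications per chain.
#' @param charge Ion charge for theoretical m/z (default -1,
#'   deprotonation).
#' @return A [SuspectList-class]. An empty rule set gives the parent-only
#'   list.
#' @examples
#' sl <- enumerateSuspects()
#' subset(candidates(sl), !is.na(class_id))
#' @export
enumerateSuspects <- function(parent = formula_parse("C12H5Cl5"),
                              rules = defaultRules(),
                              max_chain = 6L, charge = -1L) {
  stopifnot(is(parent, "ElementalFormula"))
  max_chain <- as.integer(max_chain)
  if (is.na(max_chain) || max_chain < 0L) stop("max_chain must be finite and >= 0")

  ## BFS over (formula, provenance) states; states collapse on
  ## (formula, sorted provenance counts) since constraints only see counts.
  state_key <- function(f, prov)
    paste(formulaToString(f), paste(sort(prov), collapse = ">"))
  frontier <- list(list(formula = parent, prov = character()))
  seen <- state_key(parent, character())
  states <- frontier
  depth <- 0L
  while (length(frontier) && depth < max_chain) {
    nxt <- list()
    for (st in frontier) {
      for (rule in rules) {
        if (sum(st$prov == rule@name) >= rule@maxApplications) next
        if (!isTRUE(rule@constraint(st$formula, st$prov))) next
        f2 <- tryCatch(applyRule(st$formula, rule, st$prov),
                       error = function(e) NULL)
        if (is.null(f2)) next
        prov2 <- c(st$prov, rule@name)
        k <- state_key(f2, prov2)
        if (k %in% seen) next
        seen <- c(seen, k)
        nxt[[length(nxt) + 1L]] <- list(formula = f2, prov = prov2)
      }
    }
    states <- c(states, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }

  rows <- lapply(states, function(st) {
    cls <- .classify_candidate(st$formula, st$prov)
    losses <- expectedLosses(st$prov, st$formula)
    data.frame(
      class_id = cls$class_id,
      name = cls$name,
      neutral_formula = formulaToString(st$formula),
      ion_formula = formulaToString(ionFormula(st$formula, charge)),
      theoretical_mz = ionMz(st$formula, charge),
      expected_losses = paste(losses$label, collapse = ","),
      provenance = paste(st$prov, collapse = ","),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ## dedupe by (formula, class): keep the first (shortest-chain) provenance
  key <- paste(tab$neutral_formula, tab$class_id)
  tab <- tab[!duplicated(key), , drop = FALSE]
  tab <- tab[order(is.na(tab$class_id), tab$class_id, tab$theoretical_mz), ,
             drop = FALSE]
  rownames(tab) <- NULL
  new("SuspectList", candidates = tab, parent = parent)
}

#' Write / read a suspect list as CSV
#'
#' The CSV carries the candidate table plus a `# parent:` comment header
#' so the list round-trips.
#'
#' @param x A [SuspectList-class].
#' @param path File path.
#' @return `readSuspects` returns a [SuspectList-class];
#'   `writeSuspects` returns `path` invisibly.
#' @export
writeSuspects <- function(x, path) {
  stopifnot(is(x, "SuspectList"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# parent: ", formulaToString(x@parent)), con)
  utils::write.csv(x@candidates, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSuspects
#' @export
readSuspects <- function(path) {
  first <- readLines(path, n = 1L)
  parent <- formula_parse(sub("^# parent:\\s*", "", first))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(class_id = "character"))
  tab$expected_losses[is.na(tab$expected_losses)] <- ""
  tab$provenance[is.na(tab$provenance)] <- ""
  new("SuspectList", candidates = tab, parent = parent)
}
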