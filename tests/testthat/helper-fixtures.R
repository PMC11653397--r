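# Shared fixtures: a small fast study configuration and an exhaustive
# isotopologue enumerator used as an independent oracle for the
# convolution code.

small_config <- function(...) {
  args <- utils::modifyList(list(n_per_group = 2L, n_decoys = 40L,
                                 n_blanks = 1L), list(...))
  do.call(studyConfig, args)
}

# Brute-force isotope distribution: enumerate every per-atom isotope
# assignment of a small molecule and aggregate (mass within 1e-6 Da).
# Independent of the convolution path: no shared code beyond the pinned
# isotope table.
brute_force_distribution <- function(counts) {
  iso_tab <- list(
    C = list(mass = c(12.0, 13.00335484), ab = c(0.9893, 0.0107)),
    H = list(mass = c(1.00782503, 2.01410178), ab = c(0.999885, 0.000115)),
    O = list(mass = c(15.99491462, 16.99913176, 17.99915961),
             ab = c(0.99757, 0.00038, 0.00205)),
    Cl = list(mass = c(34.96885268, 36.96590260), ab = c(0.7576, 0.2424)),
    S = list(mass = c(31.97207117, 32.97145890, 33.96786701, 35.96708071),
             ab = c(0.9499, 0.0075, 0.0425, 0.0001)))
  atoms <- rep(names(counts), counts)
  choices <- lapply(atoms, function(el) seq_along(iso_tab[[el]]$mass))
  grid <- expand.grid(choices)
  mass <- apply(grid, 1, function(idx)
    sum(mapply(function(el, i) iso_tab[[el]]$mass[i], atoms, idx)))
  ab <- apply(grid, 1, function(idx)
    prod(mapply(function(el, i) iso_tab[[el]]$ab[i], atoms, idx)))
  o <- order(mass)
  mass <- mass[o]; ab <- ab[o]
  grp <- cumsum(c(TRUE, diff(mass) > 1e-6))
  data.frame(mass = as.numeric(tapply(mass * ab, grp, sum) /
                                 tapply(ab, grp, sum)),
             abundance = as.numeric(tapply(ab, grp, sum)))
}

# Minimal hand-built SuspectList for matcher edge cases.
make_suspects <- function(tab, parent = formula_parse("C12H5Cl5")) {
  defaults <- data.frame(class_id = NA_character_, name = "x",
                         neutral_formula = "C12H5Cl5O",
                         ion_formula = "C12H4Cl5O",
                         theoretical_mz = 338.87103,
                         expected_losses = "", provenance = "OX",
                         stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (is.null(tab[[col]])) tab[[col]] <- defaults[[col]]
  new("SuspectList", candidates = tab, parent = parent)
}

# One-sample MS1 peak data.frame.
make_peaks <- function(mz, intensity = 1e6, rt = 5, sample_id = "S1",
                       level = "MS1", precursor_mz = NA_real_) {
  data.frame(sample_id = sample_id, level = level,
             precursor_mz = precursor_mz, rt_min = rt, mz = mz,
             intensity = intensity, stringsAsFactors = FALSE)
}
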