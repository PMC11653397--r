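## Pinned atomic constants. Principal-isotope (monoisotopic) masses and
## isotope abundances, IUPAC 2021 representative values. These are data,
## not tunables: the five-decimal agreement of computed [M-H]- masses with
## reference values depends on this exact table.

#' @keywords internal
.MONO_MASS <- c(
  C  = 12.0,          # by definition
  H  = 1.00782503,
  O  = 15.99491462,
  Cl = 34.96885268,
  S  = 31.97207117,
  F  = 18.99840316,
  N  = 14.00307401,
  P  = 30.97376200
)

#' @keywords internal
.ELECTRON_MASS <- 0.00054858

## Per-element isotope tables: exact mass and abundance of each stable
## isotope, principal isotope first. Abundances sum to 1 within 1e-9.
#' @keywords internal
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.00335484),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503, 2.01410178),
           abundance = c(0.999885, 0.000115)),
  O = list(mass = c(15.99491462, 16.99913176, 17.99915961),
           abundance = c(0.99757, 0.00038, 0.00205)),
  Cl = list(mass = c(34.96885268, 36.96590260),
            abundance = c(0.7576, 0.2424)),
  S = list(mass = c(31.97207117, 32.97145890, 33.96786701, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F = list(mass = 18.99840316, abundance = 1.0),
  N = list(mass = c(14.00307401, 15.00010890),
           abundance = c(0.99636, 0.00364)),
  P = list(mass = 30.97376200, abundance = 1.0)
)

## PFOS anion (C8F17SO3-), the volume-corrector ion spiked into every
## sample; its theoretical m/z is needed by the screen and the simulator.
#' @keywords internal
.PFOS_NEUTRAL <- c(C = 8, H = 1, F = 17, S = 1, O = 3)
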