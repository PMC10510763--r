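# Physical constants (CODATA 2018 exact values) and isotope abundances.

#' Physical constants used throughout the package
#'
#' Boltzmann and Planck constants are the CODATA 2018 exact SI values; the gas
#' constant is expressed in thermochemical calories so that activation
#' entropies carry the conventional cal mol^-1 K^-1 unit.
#'
#' @format A named list with elements `kB` (J K^-1), `h` (J s) and
#'   `R_cal` (cal mol^-1 K^-1).
#' @export
drl_constants <- list(
  kB    = 1.380649e-23,
  h     = 6.62607015e-34,
  R_cal = 1.98720425864083
)

# Natural isotope abundances, IUPAC 2021 representative values, aggregated at
# nominal (unit) mass offsets from the most abundant light isotope.  "D" is an
# explicit pure-deuterium element so that labelled ligands can be written
# without modelling H/D scrambling.
.iso_abundances <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  D  = 1,
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Cl = c(0.7576, 0, 0.2424),
  Co = 1,
  P  = 1,
  F  = 1
)
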