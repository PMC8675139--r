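## Physical constants (CODATA 2018) and unit conversions.
## Internal units everywhere: length Angstrom, energy eV, mass amu.
## The internal time unit is sqrt(amu * A^2 / eV); velocities are A per
## internal time unit.

#' @keywords internal
.ace_const <- list(
  kB        = 8.617333262e-5,      # Boltzmann constant, eV / K
  eV        = 1.602176634e-19,     # J
  amu       = 1.66053906660e-27,   # kg
  c_cm      = 2.99792458e10,       # speed of light, cm / s
  hbar      = 6.582119569e-16      # eV s (unused in classical MD, kept for reference)
)

## One internal time unit in femtoseconds: sqrt(amu A^2 / eV) = 10.1805... fs
.ace_time_fs <- local({
  s <- sqrt(.ace_const$amu * 1e-20 / .ace_const$eV)  # seconds
  s * 1e15
})

## Conversion from sqrt(eV / (amu A^2)) angular frequency to wavenumber cm^-1:
## nu~ = omega / (2 pi c)
.ace_freq_cm <- local({
  omega_si <- sqrt(.ace_const$eV / (.ace_const$amu * 1e-20))  # s^-1
  omega_si / (2 * pi * .ace_const$c_cm)
})

## Standard atomic weights (amu), the elements that occur in small organics.
.ace_masses <- c(
  H = 1.008, He = 4.002602, Li = 6.94, Be = 9.0121831, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998403163, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815385, Si = 28.085,
  P = 30.973761998, S = 32.06, Cl = 35.45, Ar = 39.948, K = 39.0983,
  Ca = 40.078, Br = 79.904, I = 126.90447
)

#' Atomic masses
#'
#' Look up standard atomic weights (amu) for chemical element symbols.
#'
#' @param elements character vector of element symbols, e.g. `c("C","H")`.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(elements) {
  m <- .ace_masses[elements]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
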