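# Physical constants (CODATA 2018) and unit conversions. All internal
# computation is in SI; user-facing lengths are Angstrom, energies follow the
# declared Hessian unit convention.

#' Physical constants used throughout the package
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{hbar}{Reduced Planck constant, J s.}
#'   \item{mu0}{Vacuum permeability, T^2 m^3 / J.}
#'   \item{gamma_H}{1H gyromagnetic ratio, rad s^-1 T^-1.}
#'   \item{gamma_C}{13C gyromagnetic ratio, rad s^-1 T^-1.}
#'   \item{amu}{Atomic mass unit, kg.}
#'   \item{angstrom}{1 Angstrom in m.}
#'   \item{kcalmol_A2}{1 kcal mol^-1 Angstrom^-2 in N/m.}
#' }
#' @export
sfb_constants <- list(
  kB        = 1.380649e-23,
  hbar      = 1.054571817e-34,
  mu0       = 4 * pi * 1e-7,
  gamma_H   = 2.6752218744e8,
  gamma_C   = 6.728284e7,
  amu       = 1.66053906660e-27,
  angstrom  = 1e-10,
  kcalmol_A2 = 4184 / 6.02214076e23 / 1e-20
)

# Standard atomic masses (u) for the elements that occur in small organic
# molecules; extend here if a PDB brings in something else.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA_ = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45,
  K = 39.098, CA = 40.078, FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904
)

#' Look up a standard atomic mass
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in unified atomic mass units.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .element_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unresolvable element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

# round half away from zero to `digits` decimals (the convention validated by
# the printed deviation tables; base round() is half-even). The 1e-9 guard
# keeps exact halves that lost their last bits in floating point (e.g.
# 100*9.9/440 = 2.2499999999999947) on the upward side.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
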