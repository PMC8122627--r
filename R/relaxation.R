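# Mapping of orientational spectral densities to 13C T1/T2/NOE for CH and
# CH2 probes (dipolar relaxation, optional axial CSA), percentage-deviation
# statistics against experimental tables, and the Reff grid fit.
#
# Normalization: the orientational j from the spectral solver satisfies
# G(0) = 1/5; the assembled J(omega) used in the relaxation equations is
# J = 2 Re sum_{m,m'} D^2*_{m0}(Omega_AD) D^2_{m'0}(Omega_AD) j_{m,m'}(omega)
# so that the rigid isotropic form is (2/5) tau / (1 + omega^2 tau^2). All
# interaction prefactors live here, not in the solver.

#' Dipolar coupling constant for a 13C-1H pair
#'
#' d = (mu0 / 4 pi) hbar gamma_C gamma_H / r^3, in rad/s.
#'
#' @param r_CH Bond length, Angstrom (default 1.09; note T1 scales as r^6).
#' @return Coupling constant in rad/s.
#' @export
dipolar_coupling <- function(r_CH = 1.09) {
  if (r_CH <= 0) stop("r_CH must be positive")
  cst <- sfb_constants
  cst$mu0 / (4 * pi) * cst$hbar * cst$gamma_C * cst$gamma_H /
    (r_CH * cst$angstrom)^3
}

#' Angular frequencies probed by 13C relaxation at a given spectrometer
#'
#' @param spectrometer_MHz 1H Larmor frequency in MHz.
#' @return Named vector (rad/s): `zero`, `wC`, `wHmC`, `wH`, `wHpC`.
#' @export
probe_frequencies <- function(spectrometer_MHz) {
  if (spectrometer_MHz <= 0) stop("spectrometer frequency must be positive")
  wH <- 2 * pi * spectrometer_MHz * 1e6
  wC <- wH * sfb_constants$gamma_C / sfb_constants$gamma_H
  c(zero = 0, wC = wC, wHmC = wH - wC, wH = wH, wHpC = wH + wC)
}

#' Assemble interaction spectral densities from orientational ones
#'
#' Weighted sum over body-frame indices with rank-2 Wigner weights
#' evaluated at the AF -> dipolar-frame rotation `Omega_AD`; for
#' `Omega_AD = (0, pi/2, 0)` the weights reduce to
#' (sqrt(3/8), 0, -1/2, 0, sqrt(3/8)) and for (0,0,0) only m = m' = 0
#' survives.
#'
#' @param jset A `SpectralDensitySet` covering all (m, m') pairs at the
#'   required frequencies (k = kp = 0 block).
#' @param omega_AD An [euler_angles()] rotation AF -> dipolar frame.
#' @param C Overall interaction constant multiplying the sum (default 1;
#'   relaxation prefactors are applied downstream).
#' @return data.frame with columns `omega_rad_s`, `J` (the real assembled
#'   density, s) and `J_im`.
#' @export
assemble_J <- function(jset, omega_AD, C = 1) {
  stopifnot(inherits(omega_AD, "EulerAngles"))
  wts <- as.vector(d2_m0(omega_AD$beta)) *
    exp(-1i * (-2:2) * omega_AD$alpha)      # D^2_{m,0}(alpha, beta, 0)
  omegas <- unique(jset$omega_rad_s)
  out <- data.frame(omega_rad_s = omegas, J = NA_real_, J_im = NA_real_)
  for (r in seq_along(omegas)) {
    w <- omegas[r]
    acc <- 0i
    for (a in 1:5) for (b in 1:5) {
      wa <- Conj(wts[a]) * wts[b]
      if (Mod(wa) < 1e-15) next
      acc <- acc + wa * j_lookup(jset, a - 3L, b - 3L, w)
    }
    acc <- 2 * C * acc
    out$J[r] <- Re(acc); out$J_im[r] <- Im(acc)
  }
  out
}

.J_at <- function(Jtab, w) {
  i <- which.min(abs(Jtab$omega_rad_s - w))
  if (abs(Jtab$omega_rad_s[i] - w) > 1e-6 * max(1, abs(w)))
    stop("assembled J does not cover required frequency")
  Jtab$J[i]
}

#' 13C relaxation observables from assembled spectral densities
#'
#' Standard dipolar expressions: \eqn{1/T_1 = (d^2/4)[J(\omega_H-\omega_C) +
#' 3J(\omega_C) + 6J(\omega_H+\omega_C)]}, \eqn{1/T_2 = (d^2/8)[4J(0) +
#' J(\omega_H-\omega_C) + 3J(\omega_C) + 6J(\omega_H+\omega_C) +
#' 6J(\omega_H)]}, \eqn{NOE = 1 + (\gamma_H/\gamma_C)\,\sigma\,T_1} with
#' \eqn{\sigma = (d^2/4)[6J(\omega_H+\omega_C) - J(\omega_H-\omega_C)]}.
#' CH2 probes sum the rates over both protons with their individual
#' geometry (cross-correlation neglected). Optional axial CSA contribution
#' (off by default).
#'
#' @param J_list List (one per proton) of assembled-J tables from
#'   [assemble_J()], covering the five [probe_frequencies()].
#' @param spectrometer_MHz 1H spectrometer frequency, MHz.
#' @param r_CH Effective C-H bond length, Angstrom.
#' @param csa Optional list `list(delta_sigma_ppm =, J =)` with an
#'   assembled-J table for the CSA frame; `NULL` disables CSA.
#' @return Object of class `RelaxationResult`: list with `T1_ms`, `T2_ms`,
#'   `NOE`, rates, and inputs echoed.
#' @export
relaxation_observables <- function(J_list, spectrometer_MHz, r_CH = 1.09,
                                   csa = NULL) {
  w <- probe_frequencies(spectrometer_MHz)
  d2 <- dipolar_coupling(r_CH)^2
  R1 <- R2 <- sigma <- 0
  for (Jt in J_list) {
    J0 <- .J_at(Jt, 0); JC <- .J_at(Jt, w["wC"])
    JmC <- .J_at(Jt, w["wHmC"]); JH <- .J_at(Jt, w["wH"])
    JpC <- .J_at(Jt, w["wHpC"])
    R1 <- R1 + d2 / 4 * (JmC + 3 * JC + 6 * JpC)
    R2 <- R2 + d2 / 8 * (4 * J0 + JmC + 3 * JC + 6 * JpC + 6 * JH)
    sigma <- sigma + d2 / 4 * (6 * JpC - JmC)
  }
  if (!is.null(csa)) {
    ds <- csa$delta_sigma_ppm * 1e-6
    JC <- .J_at(csa$J, w["wC"]); J0 <- .J_at(csa$J, 0)
    R1 <- R1 + (ds * w["wC"])^2 / 3 * JC
    R2 <- R2 + (ds * w["wC"])^2 / 18 * (4 * J0 + 3 * JC)
  }
  if (R1 <= 0 || R2 <= 0)
    stop("nonpositive relaxation rate: inconsistent spectral densities")
  noe <- 1 + sfb_constants$gamma_H / sfb_constants$gamma_C * sigma / R1
  structure(list(T1_ms = unname(1000 / R1), T2_ms = unname(1000 / R2),
                 NOE = unname(noe), R1_s = unname(R1), R2_s = unname(R2),
                 sigma_s = unname(sigma),
                 spectrometer_MHz = spectrometer_MHz, r_CH = r_CH,
                 n_protons = length(J_list), csa = !is.null(csa)),
            class = "RelaxationResult")
}

#' @export
print.RelaxationResult <- function(x, ...) {
  cat(sprintf("T1 = %.1f ms, T2 = %.1f ms, NOE = %.3f (CH%s, %.1f MHz)\n",
              x$T1_ms, x$T2_ms, x$NOE,
              if (x$n_protons == 2) "2" else "", x$spectrometer_MHz))
  invisible(x)
}

#' Percentage deviation from an experimental value
#'
#' e = 100 |calc - exp| / exp, rounded half-up to 1 decimal (the printed
#' convention of the deviation tables).
#'
#' @param exp_value Experimental value (> 0).
#' @param calc_value Calculated value.
#' @return Deviation in percent.
#' @export
percentage_deviation <- function(exp_value, calc_value) {
  if (any(exp_value <= 0)) stop("experimental value must be positive")
  round_half_up(100 * abs(calc_value - exp_value) / exp_value, 1)
}

#' Deviation statistics over a table of (exp, calc) pairs
#'
#' @param table data.frame with columns `observable` (e.g. "T1", "T2",
#'   "NOE"), `exp`, `calc`.
#' @return Object of class `DeviationReport`: `per_entry` (with `e`
#'   percent), `summary` (per-observable `mean_e`, `max_e`, both over the
#'   rounded cells, reported to 1 decimal), and `ss` (sum of squared
#'   unrounded percentage deviations, the Reff fitting objective).
#' @export
deviation_summary <- function(table) {
  stopifnot(nrow(table) > 0, all(c("observable", "exp", "calc") %in%
                                   names(table)))
  keep <- is.finite(table$exp) & is.finite(table$calc)
  table <- table[keep, , drop = FALSE]
  if (!nrow(table)) stop("no finite (exp, calc) pairs")
  e_raw <- 100 * abs(table$calc - table$exp) / table$exp
  table$e <- round_half_up(e_raw, 1)
  obs <- unique(table$observable)
  summ <- do.call(rbind, lapply(obs, function(o) {
    ei <- table$e[table$observable == o]
    data.frame(observable = o, n = length(ei),
               mean_e = round_half_up(mean(ei), 1),
               max_e = round_half_up(max(ei), 1))
  }))
  structure(list(per_entry = table, summary = summ, ss = sum(e_raw^2)),
            class = "DeviationReport")
}

#' @export
print.DeviationReport <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("sum of squared deviations: %.1f\n", x$ss))
  invisible(x)
}

#' Read an experimental relaxation table
#'
#' CSV with columns `system, probe, freq_MHz, T1_ms, T2_ms, NOE` (missing
#' values allowed).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_experiment_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("freq_MHz", "T1_ms", "T2_ms", "NOE")
  if (!all(need %in% names(tab)))
    stop("experimental table must have columns freq_MHz, T1_ms, T2_ms, NOE")
  tab
}
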