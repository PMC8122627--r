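# Bead-model hydrodynamics: per-bead Stokes friction with the effective
# atomic radius Reff as the single adjustable parameter, assembly of the
# generalized friction tensor over rotational + internal velocities, and the
# rotational diffusion tensor defining the attached frame (AF).

#' Per-bead translational Stokes friction
#'
#' @param Reff Effective hydrodynamic atomic radius, Angstrom.
#' @param eta Solvent viscosity, Pa s.
#' @param bc Boundary condition, `"stick"` (6 pi eta R) or `"slip"`
#'   (4 pi eta R).
#' @return Friction coefficient zeta in kg/s.
#' @export
bead_friction <- function(Reff, eta, bc = c("stick", "slip")) {
  bc <- match.arg(bc)
  if (!is.finite(Reff) || Reff <= 0) stop("Reff must be positive")
  if (!is.finite(eta) || eta <= 0) stop("viscosity must be positive")
  C <- if (bc == "stick") 6 else 4
  C * pi * eta * Reff * sfb_constants$angstrom
}

# Rotne-Prager-Yamakawa pairwise mobility correction; returns the 3n x 3n
# friction matrix Z = mobility^-1 (kg/s). zeta: per-bead frictions (0 = no
# bead); pos_m positions in metres.
.rp_friction <- function(zeta, pos_m, eta, Reff_m) {
  act <- which(zeta > 0)
  na <- length(act)
  mob <- matrix(0, 3 * na, 3 * na)
  for (ii in seq_len(na)) {
    a <- act[ii]
    mob[3 * ii - 2:0, 3 * ii - 2:0] <- diag(3) / zeta[a]
    for (jj in seq_len(na)) {
      if (jj == ii) next
      b <- act[jj]
      rv <- pos_m[a, ] - pos_m[b, ]
      r <- sqrt(sum(rv^2))
      rh <- outer(rv, rv) / r^2
      blk <- if (r >= 2 * Reff_m) {
        (diag(3) + rh + (2 * Reff_m^2 / r^2) * (diag(3) / 3 - rh)) /
          (8 * pi * eta * r)
      } else {
        ((1 - 9 * r / (32 * Reff_m)) * diag(3) +
           (3 * r / (32 * Reff_m)) * rh) / (6 * pi * eta * Reff_m)
      }
      mob[3 * ii - 2:0, 3 * jj - 2:0] <- blk
    }
  }
  Zi <- solve(mob)
  Z <- matrix(0, 3 * length(zeta), 3 * length(zeta))
  for (ii in seq_len(na)) for (jj in seq_len(na)) {
    Z[3 * act[ii] - 2:0, 3 * act[jj] - 2:0] <- Zi[3 * ii - 2:0, 3 * jj - 2:0]
  }
  Z
}

#' Generalized friction tensor at the reference structure
#'
#' Assembles Xi = B^T Z B where Z is the per-bead friction (free-draining by
#' default, optional Rotne-Prager correction) and B maps rotational plus
#' internal mode velocities to bead Cartesian velocities. The rotational
#' block is taken about the centre of diffusion (friction-weighted centroid)
#' and rigid translation is projected out of every velocity column.
#'
#' @param structure A [molecular_structure()].
#' @param internal_basis 3n x n_int matrix of Cartesian displacements per
#'   unit mass-weighted mode coordinate (kg^-1/2), as from
#'   [internal_modes()]; may be `NULL` / zero columns for a rigid body.
#' @param Reff Effective atomic radius, Angstrom.
#' @param eta Viscosity, Pa s.
#' @param bc `"stick"` or `"slip"`.
#' @param hydrodynamic_interaction `"none"` (free-draining) or
#'   `"rotne_prager"`.
#' @param bead_selection `"all"` (hydrogens carry beads too, default) or
#'   `"heavy"`.
#' @return Object of class `FrictionTensor` with blocks `Xi_RR` (3 x 3,
#'   J s), `Xi_II` (n_int x n_int, s^-1), `Xi_RI` (3 x n_int), the
#'   `center_of_diffusion` (Angstrom), and tags.
#' @export
friction_tensor <- function(structure, internal_basis = NULL, Reff, eta,
                            bc = c("stick", "slip"),
                            hydrodynamic_interaction = c("none", "rotne_prager"),
                            bead_selection = c("all", "heavy")) {
  bc <- match.arg(bc)
  hydrodynamic_interaction <- match.arg(hydrodynamic_interaction)
  bead_selection <- match.arg(bead_selection)
  n <- length(structure$atom_id)
  pos_m <- structure$position * sfb_constants$angstrom
  zeta1 <- bead_friction(Reff, eta, bc)
  zeta <- rep(zeta1, n)
  if (bead_selection == "heavy") zeta[structure$element %in% c("H", "D")] <- 0
  if (all(zeta == 0)) stop("no beads selected")
  cod <- colSums(pos_m * zeta) / sum(zeta)

  A <- internal_basis
  if (is.null(A)) A <- matrix(0, 3 * n, 0)
  nint <- ncol(A)
  BR <- matrix(0, 3 * n, 3)
  e <- diag(3)
  for (p in 1:3) {
    w <- t(vapply(seq_len(n),
                  function(a) crossprod_vec(e[p, ], pos_m[a, ] - cod),
                  numeric(3)))
    BR[, p] <- as.vector(t(w))
  }
  B <- cbind(BR, A)
  # project out rigid translation (friction-weighted mean velocity)
  zrep <- rep(zeta, each = 3)
  for (p in 1:3) {
    idx <- seq(p, 3 * n, by = 3)
    mean_v <- colSums(B[idx, , drop = FALSE] * zeta) / sum(zeta)
    B[idx, ] <- sweep(B[idx, , drop = FALSE], 2, mean_v)
  }
  Xi <- if (hydrodynamic_interaction == "none") {
    t(B) %*% (zrep * B)
  } else {
    Z <- .rp_friction(zeta, pos_m, eta, Reff * sfb_constants$angstrom)
    t(B) %*% Z %*% B
  }
  Xi <- (Xi + t(Xi)) / 2
  if (nint > 0) {
    # conditioning check on unit-normalized columns (rotational and internal
    # columns carry different physical units); a zero axial rotation column
    # is legitimate for linear geometries, zero internal columns are not
    cn <- sqrt(colSums(B^2))
    if (any(cn[-(1:3)] == 0))
      stop("rank-deficient velocity Jacobian (mode ",
           which(cn[-(1:3)] == 0)[1], ")")
    nzc <- which(cn > 0)
    sv <- svd(sweep(B[, nzc, drop = FALSE], 2, cn[nzc], "/"),
              nu = 0, nv = 0)$d
    if (min(sv) < 1e-10 * max(sv))
      stop("rank-deficient velocity Jacobian (mode ", nzc[which.min(sv)], ")")
  }
  structure(list(
    Xi_RR = Xi[1:3, 1:3, drop = FALSE],
    Xi_RI = Xi[1:3, -(1:3), drop = FALSE],
    Xi_II = Xi[-(1:3), -(1:3), drop = FALSE],
    center_of_diffusion = cod / sfb_constants$angstrom,
    boundary_condition = bc, Reff = Reff, eta = eta,
    hydrodynamic_interaction = hydrodynamic_interaction,
    bead_selection = bead_selection),
    class = "FrictionTensor")
}

#' Rotational diffusion tensor and attached-frame definition
#'
#' D = kB T (Xi_RR)^-1. The attached frame (AF) is the principal frame of D
#' centred at the centre of diffusion, with z the largest-D
#' (smallest-friction) axis. Axis signs are fixed deterministically (largest
#' magnitude component positive, y = z x x).
#'
#' @param friction A [friction_tensor()] (or a bare 3 x 3 Xi_RR matrix).
#' @param temperature Kelvin.
#' @return Object of class `DiffusionTensor`: `D` (3 x 3, s^-1), principal
#'   `values` (ascending D1 <= D2 <= D3), `axes` (columns x,y,z of the AF in
#'   input coordinates), `origin` (Angstrom), `tau_c` = 1/(6 D_iso).
#' @export
diffusion_tensor <- function(friction, temperature) {
  if (inherits(friction, "FrictionTensor")) {
    Xi <- friction$Xi_RR
    origin <- friction$center_of_diffusion
  } else {
    Xi <- as.matrix(friction)
    origin <- c(0, 0, 0)
  }
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  ev <- eigen((Xi + t(Xi)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values))
    stop("singular rotational friction block (collinear beads?)")
  D <- sfb_constants$kB * temperature * solve(Xi)
  D <- (D + t(D)) / 2
  ed <- eigen(D, symmetric = TRUE)
  ord <- order(ed$values)            # ascending: D1 <= D2 <= D3
  vals <- ed$values[ord]
  V <- ed$vectors[, ord, drop = FALSE]
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  z <- fix_sign(V[, 3]); x <- fix_sign(V[, 1])
  y <- crossprod_vec(z, x)
  axes <- cbind(x, y, z)
  Diso <- mean(vals)
  structure(list(D = D, values = vals, axes = axes, origin = origin,
                 temperature = temperature, tau_c = 1 / (6 * Diso)),
            class = "DiffusionTensor")
}

#' @export
print.DiffusionTensor <- function(x, ...) {
  cat(sprintf("DiffusionTensor: D = (%.3e, %.3e, %.3e) s^-1, tau_c = %.3e s\n",
              x$values[1], x$values[2], x$values[3], x$tau_c))
  invisible(x)
}
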