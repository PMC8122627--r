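# Construction of the SFB (semi-flexible Brownian) parameters: the N = 6n-9
# dimensionless modes x = (q~, p~, L~) built from Eckart-projected normal
# coordinates, their momenta and the body-frame angular momentum, the drift
# matrix omega_io (N x N, s^-1) of their linearized phase-space dynamics and
# the coupling omega_int (N x 3, s^-1) of the angular-momentum modes to the
# body-frame rotation generators.
#
# Conventions: mass-weighted normal coordinate Q_k (eigenfrequency w_k),
#   q~_k = w_k Q_k / sqrt(kB T),  p~_k = P_k / sqrt(kB T),
#   L~ = (kB T)^-1/2 I^-1/2 L  (I = inertia tensor in the attached frame,
#   taken about the centre of diffusion).
# Each mode has unit equilibrium variance, so the stationary density is the
# standard Gaussian p(x) and the FP operator annihilates it by construction.

#' Internal harmonic modes from the projected Hessian
#'
#' @param hessian A [hessian_matrix()].
#' @param structure The matching [molecular_structure()]; if `structure$rigid`
#'   the result has zero modes.
#' @param tol Relative tolerance for the zero-mode threshold.
#' @return A list: `omega` (mode frequencies, rad/s, ascending), `U` (3n x
#'   n_int mass-weighted orthonormal eigenvectors), `A` (3n x n_int Cartesian
#'   displacement Jacobian, kg^-1/2), `n_internal`, `linear` flag.
#' @export
internal_modes <- function(hessian, structure, tol = 1e-8) {
  n <- length(structure$atom_id)
  linear <- is_linear_geometry(structure)
  n_int <- if (linear) 3L * n - 5L else 3L * n - 6L
  if (structure$rigid || n_int == 0L) {
    return(list(omega = numeric(0), U = matrix(0, 3 * n, 0),
                A = matrix(0, 3 * n, 0), n_internal = 0L, linear = linear))
  }
  pr <- projected_mass_weighted_hessian(hessian, structure)
  es <- eigen(pr$H, symmetric = TRUE)
  scale <- max(abs(es$values))
  pos <- es$values > tol * scale
  if (any(es$values < -tol * scale))
    stop("negative projected Hessian eigenvalue: not a local minimum")
  if (sum(pos) != n_int)
    stop(sprintf("expected %d internal modes, found %d positive eigenvalues",
                 n_int, sum(pos)))
  idx <- which(pos)[order(es$values[pos])]
  U <- es$vectors[, idx, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(U))) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  m_kg <- structure$mass * sfb_constants$amu
  A <- U / rep(sqrt(m_kg), each = 3)
  list(omega = sqrt(es$values[idx]), U = U, A = A,
       n_internal = as.integer(n_int), linear = linear)
}

# inverse symmetric square root
inv_sqrtm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop("matrix not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

new_sfb_parameters <- function(omega_io, omega_int, labels, temperature,
                               meta = list()) {
  structure(list(omega_io = omega_io, omega_int = omega_int,
                 labels = labels, N = nrow(omega_io),
                 temperature = temperature, meta = meta),
            class = "SFBParameters")
}

#' @export
print.SFBParameters <- function(x, ...) {
  cat(sprintf("SFBParameters: N = %d (%d coord, %d momentum, %d ang-mom), T = %g K\n",
              x$N, sum(x$labels == "coordinate"),
              sum(x$labels == "momentum"),
              sum(x$labels == "angular-momentum"), x$temperature))
  invisible(x)
}

#' SFB parameters for a rigid rotor with prescribed tensors
#'
#' Reduces the construction to its inertial-rotor closed form: for isotropic
#' inertia I and friction xi, `omega_io = (xi/I) 1_3` and
#' `omega_int = sqrt(kB T / I) 1_3`.
#'
#' @param inertia 3-vector of principal inertia values (kg m^2) or 3 x 3
#'   tensor.
#' @param xi_rr 3-vector of principal rotational frictions (J s) or 3 x 3
#'   tensor, in the same axes.
#' @param temperature Kelvin.
#' @return An `SFBParameters` object with the 3 angular-momentum modes only.
#' @export
sfb_rigid_rotor <- function(inertia, xi_rr, temperature) {
  I <- if (is.matrix(inertia)) inertia else diag(inertia)
  Xi <- if (is.matrix(xi_rr)) xi_rr else diag(xi_rr)
  Iih <- inv_sqrtm(I)
  W <- Iih %*% Xi %*% Iih
  om_int <- sqrt(sfb_constants$kB * temperature) * t(Iih)
  new_sfb_parameters(W, om_int, rep("angular-momentum", 3), temperature,
                     meta = list(inertia = I, Xi_RR = Xi, rigid = TRUE))
}

#' Build the SFB drift and coupling matrices
#'
#' Assembles the linearized phase-space dynamics of the dimensionless modes:
#' Hamiltonian streaming couples each coordinate/momentum pair
#' antisymmetrically at its mode frequency, dissipation acts on the momentum
#' and angular-momentum modes through the friction blocks, and the
#' angular-momentum modes feed the body-frame rotation generators with rates
#' `sqrt(kB T) I^-1/2`. Second-order precession terms are dropped.
#'
#' Everything is expressed in the attached frame (AF): the principal frame of
#' the rotational diffusion tensor, centred at the centre of diffusion, with
#' z the smallest-friction axis. For linear geometries the axial
#' angular-momentum mode (vanishing inertia and friction) is removed and
#' N = 2(3n-5) + 2.
#'
#' @param structure A [molecular_structure()].
#' @param hessian A [hessian_matrix()] (ignored for rigid structures).
#' @param friction A [friction_tensor()] computed at the same geometry with
#'   `internal_basis` consistent with [internal_modes()] of this Hessian.
#' @param temperature Kelvin.
#' @param modes Optional precomputed [internal_modes()] result.
#' @param zero_coupling If `TRUE`, zero the internal-rotational friction
#'   coupling block (diagnostic).
#' @return An `SFBParameters` object. `meta` carries the AF definition
#'   (axes, origin), inertia, the diffusion tensor and mode frequencies.
#' @export
build_sfb <- function(structure, hessian, friction, temperature,
                      modes = NULL, zero_coupling = FALSE) {
  kB <- sfb_constants$kB
  if (is.null(modes)) modes <- internal_modes(hessian, structure)
  nint <- modes$n_internal
  if (nint > 0 && ncol(friction$Xi_RI) != nint)
    stop("friction internal block does not match the internal mode count")

  linear <- modes$linear
  if (linear) {
    # AF axes from Xi_RR directly (diffusion tensor is singular about the
    # molecular axis); keep the two perpendicular angular-momentum modes.
    eXi <- eigen((friction$Xi_RR + t(friction$Xi_RR)) / 2, symmetric = TRUE)
    ord <- order(eXi$values, decreasing = TRUE)  # z = smallest friction
    E <- eXi$vectors[, ord, drop = FALSE]
    for (j in 1:3) if (E[which.max(abs(E[, j])), j] < 0) E[, j] <- -E[, j]
    E[, 2] <- crossprod_vec(E[, 3], E[, 1])
    keepL <- 1:2
    dif <- NULL
  } else {
    dif <- diffusion_tensor(friction, temperature)
    E <- dif$axes
    keepL <- 1:3
  }
  Xi_RR <- t(E) %*% friction$Xi_RR %*% E
  Xi_RI <- t(E) %*% friction$Xi_RI
  if (zero_coupling && length(Xi_RI)) Xi_RI[] <- 0
  Iaf <- t(E) %*% inertia_tensor(structure,
                                 about = friction$center_of_diffusion) %*% E
  Iih3 <- matrix(0, 3, 3)
  Iih3[keepL, keepL] <- inv_sqrtm(Iaf[keepL, keepL, drop = FALSE])
  nL <- length(keepL)

  N <- 2L * nint + nL
  W <- matrix(0, N, N)
  om_int <- matrix(0, N, 3)
  iq <- seq_len(nint)
  ip <- nint + iq
  iL <- 2L * nint + seq_len(nL)
  if (nint > 0) {
    wk <- modes$omega
    W[iq, ip] <- diag(-wk, nint)
    W[ip, iq] <- diag(wk, nint)
    W[ip, ip] <- friction$Xi_II
    # Xi_RI rows are AF axes 1:3; restrict to the kept angular-momentum axes
    cpl <- t(Xi_RI[keepL, , drop = FALSE]) %*% Iih3[keepL, keepL, drop = FALSE]
    W[ip, iL] <- cpl
    W[iL, ip] <- t(cpl)
  }
  W[iL, iL] <- Iih3[keepL, keepL, drop = FALSE] %*%
    Xi_RR[keepL, keepL, drop = FALSE] %*% Iih3[keepL, keepL, drop = FALSE]
  om_int[iL, keepL] <- sqrt(kB * temperature) *
    t(Iih3[keepL, keepL, drop = FALSE])
  labels <- c(rep("coordinate", nint), rep("momentum", nint),
              rep("angular-momentum", nL))
  new_sfb_parameters(
    W, om_int, labels, temperature,
    meta = list(af_axes = E, af_origin = friction$center_of_diffusion,
                inertia_af = Iaf, diffusion = dif, mode_frequencies =
                  if (nint) modes$omega else numeric(0),
                linear = linear, Reff = friction$Reff, eta = friction$eta,
                boundary_condition = friction$boundary_condition))
}

#' Serialize SFB parameters to a plain-text archive
#'
#' Writes a small self-describing text file (header lines `# key value`,
#' then `omega_io` and `omega_int` as whitespace-delimited blocks) that
#' [read_sfb_parameters()] restores.
#'
#' @param params An `SFBParameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sfb_parameters <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# N %d", params$N),
               sprintf("# temperature %.17g", params$temperature),
               paste("# labels", paste(params$labels, collapse = " ")),
               "# omega_io"), con)
  utils::write.table(format(params$omega_io, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("# omega_int", con)
  utils::write.table(format(params$omega_int, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sfb_parameters
#' @export
read_sfb_parameters <- function(path) {
  lines <- readLines(path)
  N <- as.integer(strsplit(lines[1], " ")[[1]][3])
  temperature <- as.numeric(strsplit(lines[2], " ")[[1]][3])
  labels <- strsplit(lines[3], " ")[[1]][-(1:2)]
  i_io <- which(lines == "# omega_io")
  i_int <- which(lines == "# omega_int")
  parse_block <- function(lns) {
    do.call(rbind, lapply(strsplit(trimws(lns), "[[:space:]]+"),
                          function(x) as.numeric(x)))
  }
  W <- parse_block(lines[(i_io + 1):(i_int - 1)])
  V <- parse_block(lines[(i_int + 1):length(lines)])
  new_sfb_parameters(W, V, labels, temperature)
}

#' Residual of the equilibrium state under the discretized operator
#'
#' Applies the Hermite-space discretization of the Fokker-Planck operator to
#' the (symmetrized) equilibrium vector and returns the residual norm
#' relative to the operator norm. `variance_scale != 1` substitutes a
#' Gaussian of that variance for the equilibrium state, breaking the
#' fluctuation-dissipation balance: the residual then becomes strictly
#' positive (negative control).
#'
#' @param params An `SFBParameters` object.
#' @param nu_max Hermite excitation cutoff (even values resolve the scaled
#'   Gaussian).
#' @param variance_scale Variance of the trial Gaussian (1 = equilibrium).
#' @return Scalar relative residual.
#' @export
stationarity_residual <- function(params, nu_max = 4, variance_scale = 1) {
  op <- build_operator(params, nu_max = nu_max, L = 0)
  v <- equilibrium_vector(op, variance_scale = variance_scale)
  r <- operator_apply(op, v)
  nrm <- operator_norm(op)
  if (nrm == 0) return(0)
  sqrt(sum(Mod(r)^2)) / nrm
}
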