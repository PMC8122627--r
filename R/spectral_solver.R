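# Reference solver for orientational spectral densities under the SFB
# operator: the operator is discretized in the product basis
# {D^2_{k,m}(Omega)} x {Hermite states of total excitation <= nu_max} and the
# resolvent (i omega + Gamma)^-1 is applied to equilibrium-weighted Wigner
# starting vectors. The Ornstein-Uhlenbeck part is the number-quadratic boson
# form Gamma_0 = sum_ij omega^io_ij b_i^+ b_j; the rotational coupling
# Gamma_int = -i sum_ip omega^int_ip (b_i + b_i^+) J_p changes the Hermite
# excitation by +-1 and m by 0, +-1. Blocks with different lab index k are
# identical and uncoupled, so j is computed once per (m, m') pair.

# ---- Hermite product basis ------------------------------------------------

# all multi-indices of length N with sum <= nu_max, ordered by total
# excitation then reverse-lexicographically (deterministic)
hermite_basis <- function(N, nu_max) {
  gen <- function(N, s) {
    if (N == 1L) return(matrix(s, ncol = 1))
    do.call(rbind, lapply(0:s, function(a) cbind(a, gen(N - 1L, s - a))))
  }
  out <- do.call(rbind, lapply(0:nu_max, function(s) gen(N, s)))
  dimnames(out) <- NULL
  out
}

basis_keys <- function(B) apply(B, 1, paste, collapse = ",")

# ---- operator assembly ----------------------------------------------------

#' Discretized SFB operator
#'
#' @param params An `SFBParameters` object.
#' @param nu_max Hermite excitation cutoff (>= 1).
#' @param L Orientational rank block: 2 (default, relaxation) or 0
#'   (equilibrium/stationarity checks; the rotational coupling vanishes).
#' @param max_dim Basis-size budget; exceeding it raises a resource error
#'   suggesting [mode_reduction()].
#' @return Object of class `OperatorMatrix`: triplet storage (`i`, `j`,
#'   `z`), cached sparse real/imaginary parts, the Hermite `basis`, index
#'   maps and metadata.
#' @export
build_operator <- function(params, nu_max = 4, L = 2, max_dim = 20000) {
  stopifnot(nu_max >= 1)
  N <- params$N
  L <- as.integer(L)
  B <- hermite_basis(N, nu_max)
  nherm <- nrow(B)
  nm <- 2L * L + 1L
  dim_ <- as.integer(nherm * nm)
  if (dim_ > max_dim)
    stop(sprintf(paste0("operator dimension %d exceeds budget %d; ",
                        "reduce modes with mode_reduction()"), dim_, max_dim))
  keys <- basis_keys(B)
  tot <- rowSums(B)
  W <- params$omega_io
  V <- params$omega_int

  ti <- integer(0); tj <- integer(0); tz <- complex(0)
  add <- function(i, j, z) {
    ti <<- c(ti, i); tj <<- c(tj, j); tz <<- c(tz, z)
  }

  # Gamma_0 diagonal in the Hermite block: sum_i omega_ii n_i
  diag_h <- as.vector(B %*% diag(W)[seq_len(N)])
  # off-diagonal omega_ij b_i^+ b_j (i != j)
  h_tr <- list(i = integer(0), j = integer(0), x = numeric(0))
  nz <- which(W != 0 & !diag(N) == 1, arr.ind = TRUE)
  if (nrow(nz)) {
    for (r in seq_len(nrow(nz))) {
      i <- nz[r, 1]; j <- nz[r, 2]
      src <- which(B[, j] > 0L)
      if (!length(src)) next
      tgt <- B[src, , drop = FALSE]
      tgt[, j] <- tgt[, j] - 1L
      tgt[, i] <- tgt[, i] + 1L
      dst <- match(apply(tgt, 1, paste, collapse = ","), keys)
      amp <- W[i, j] * sqrt(B[src, j] * (B[src, i] + 1))
      h_tr$i <- c(h_tr$i, dst); h_tr$j <- c(h_tr$j, src)
      h_tr$x <- c(h_tr$x, amp)
    }
  }

  if (L == 0) {
    # single m block
    add(seq_len(nherm), seq_len(nherm), diag_h + 0i)
    if (length(h_tr$i)) add(h_tr$i, h_tr$j, h_tr$x + 0i)
  } else {
    for (mb in seq_len(nm)) {
      off <- (mb - 1L) * nherm
      add(off + seq_len(nherm), off + seq_len(nherm), diag_h + 0i)
      if (length(h_tr$i)) add(off + h_tr$i, off + h_tr$j, h_tr$x + 0i)
    }
    # Gamma_int: -i sum_ip V_ip x_i J_p
    J <- angular_momentum_matrices(L)
    Jm <- list(J$Jx, J$Jy, J$Jz)
    act <- which(rowSums(abs(V)) > 0)
    for (i in act) {
      # x_i = b_i + b_i^+ triplets in the Hermite factor
      lo_src <- which(B[, i] > 0L)
      lo_tgt <- B[lo_src, , drop = FALSE]; lo_tgt[, i] <- lo_tgt[, i] - 1L
      lo_dst <- match(apply(lo_tgt, 1, paste, collapse = ","), keys)
      lo_amp <- sqrt(B[lo_src, i])
      hi_src <- which(tot < nu_max)
      hi_tgt <- B[hi_src, , drop = FALSE]; hi_tgt[, i] <- hi_tgt[, i] + 1L
      hi_dst <- match(apply(hi_tgt, 1, paste, collapse = ","), keys)
      hi_amp <- sqrt(B[hi_src, i] + 1)
      xs <- c(lo_src, hi_src); xd <- c(lo_dst, hi_dst)
      xa <- c(lo_amp, hi_amp)
      for (p in 1:3) {
        if (V[i, p] == 0) next
        Jp <- Jm[[p]]
        jnz <- which(Jp != 0, arr.ind = TRUE)
        for (r in seq_len(nrow(jnz))) {
          mrow <- jnz[r, 1]; mcol <- jnz[r, 2]
          val <- -1i * V[i, p] * Jp[mrow, mcol]
          add((mrow - 1L) * nherm + xd, (mcol - 1L) * nherm + xs, val * xa)
        }
      }
    }
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = Re(tz), dims = c(dim_, dim_))
  Bm <- Matrix::sparseMatrix(i = ti, j = tj, x = Im(tz), dims = c(dim_, dim_))
  structure(list(i = ti, j = tj, z = tz, dim = dim_, nherm = nherm, nm = nm,
                 L = L, basis = B, keys = keys, nu_max = nu_max,
                 params = params, A_re = A, A_im = Bm),
            class = "OperatorMatrix")
}

#' @export
print.OperatorMatrix <- function(x, ...) {
  cat(sprintf("OperatorMatrix: dim %d (L = %d, %d Hermite states, nu_max %d), nnz %d\n",
              x$dim, x$L, x$nherm, x$nu_max, length(x$z)))
  invisible(x)
}

# apply Gamma to a complex vector
operator_apply <- function(op, v) {
  vr <- Re(v); vi <- Im(v)
  as.vector(op$A_re %*% vr - op$A_im %*% vi) +
    1i * as.vector(op$A_re %*% vi + op$A_im %*% vr)
}

operator_norm <- function(op) sqrt(sum(Mod(op$z)^2))

# row index of m-state (m in -L..L) at Hermite ground state
.v_index <- function(op, m) (m + op$L) * op$nherm + 1L

# equilibrium-weighted Wigner starting vector (1/sqrt(2L+1)) |m> x |0>
starting_vector <- function(op, m) {
  v <- numeric(op$dim)
  v[.v_index(op, m)] <- 1 / sqrt(op$nm)
  v
}

# Hermite-function coefficients of a centred Gaussian density of variance s2,
# divided by the square root of the standard Gaussian (numeric quadrature)
.gauss_hermite_coeffs <- function(nmax, s2) {
  x <- seq(-25, 25, length.out = 20001)
  target <- exp(-x^2 / (2 * s2)) / sqrt(2 * pi * s2) *
    (2 * pi)^(1 / 4) * exp(x^2 / 4)
  # orthonormal Hermite functions psi_n = He_n(x) e^{-x^2/4}/sqrt(n! sqrt(2pi))
  psi <- matrix(0, length(x), nmax + 1)
  He_prev <- rep(1, length(x)); He <- x
  psi[, 1] <- He_prev
  if (nmax >= 1) psi[, 2] <- He
  if (nmax >= 2) for (n in 2:nmax) {
    He_new <- x * He - (n - 1) * He_prev
    He_prev <- He; He <- He_new
    psi[, n + 1] <- He
  }
  w <- exp(-x^2 / 4)
  dx <- x[2] - x[1]
  vapply(0:nmax, function(n) {
    sum(psi[, n + 1] * w * target) * dx / sqrt(factorial(n) * sqrt(2 * pi))
  }, numeric(1))
}

# discretized equilibrium state (variance_scale = 1 gives the exact ground
# vector); only meaningful for L = 0 operators
equilibrium_vector <- function(op, variance_scale = 1) {
  stopifnot(op$L == 0)
  if (variance_scale == 1) {
    v <- numeric(op$dim); v[1] <- 1
    return(v)
  }
  cn <- .gauss_hermite_coeffs(op$nu_max, variance_scale)
  v <- apply(op$basis, 1, function(n) prod(cn[n + 1]))
  v / sqrt(sum(v^2))
}

# solve (Gamma + i w) y = b (b real or complex) via the real 2x-size form
resolvent_solve <- function(op, omega, b) {
  d <- op$dim
  A <- op$A_re
  Bm <- op$A_im + Matrix::Diagonal(d, omega)
  M <- rbind(cbind(A, -Bm), cbind(Bm, A))
  rhs <- c(Re(b), Im(b))
  y <- as.vector(Matrix::solve(M, rhs))
  y[1:d] + 1i * y[d + 1:d]
}

#' Orientational spectral densities from the SFB operator
#'
#' Computes \eqn{j_{m,m'}^{(k,k')}(\omega) =
#' \langle v_{k',m'} | (i\omega + \Gamma)^{-1} | v_{k,m}\rangle} with
#' equilibrium-weighted Wigner starting vectors, normalized so that the
#' isotropic rigid-rotor diagonal value is \eqn{(1/5)\tau/(1+\omega^2\tau^2)}.
#' Blocks with \eqn{k \ne k'} vanish identically (isotropic equilibrium) and
#' are returned as zero without solving.
#'
#' @param op An [build_operator()] result (L = 2).
#' @param k,kp Lab-frame indices in -2..2.
#' @param m,mp Integer vectors of body-frame indices in -2..2; all (m, mp)
#'   combinations are returned.
#' @param omegas Numeric vector of angular frequencies, rad/s.
#' @return Object of class `SpectralDensitySet`: a data.frame with columns
#'   `k, kp, m, mp, omega_rad_s, re_j_s, im_j_s`.
#' @export
spectral_density <- function(op, k = 0, kp = 0, m = -2:2, mp = -2:2, omegas) {
  stopifnot(op$L == 2, all(abs(c(k, kp, m, mp)) <= 2))
  # no dissipation -> Gamma singular at omega = 0
  if (any(omegas == 0) &&
      (length(op$A_re@x) == 0 || max(abs(op$A_re@x)) == 0))
    stop("Gamma has no dissipative part: j(0) undefined")
  d <- op$dim
  rows <- list()
  if (k != kp) {
    grid <- expand.grid(m = m, mp = mp, omega_rad_s = omegas)
    out <- data.frame(k = k, kp = kp, grid[c("m", "mp", "omega_rad_s")],
                      re_j_s = 0, im_j_s = 0)
    class(out) <- c("SpectralDensitySet", class(out))
    return(out)
  }
  rhs <- vapply(m, function(mm) starting_vector(op, mm), numeric(d))
  proj <- vapply(mp, function(mm) starting_vector(op, mm), numeric(d))
  for (w in omegas) {
    A <- op$A_re
    Bm <- op$A_im + Matrix::Diagonal(d, w)
    M <- rbind(cbind(A, -Bm), cbind(Bm, A))
    Y <- as.matrix(Matrix::solve(M, rbind(rhs, matrix(0, d, length(m)))))
    for (a in seq_along(m)) {
      yc <- Y[1:d, a] + 1i * Y[d + 1:d, a]
      jv <- as.vector(t(proj) %*% yc)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, kp = kp, m = m[a], mp = mp, omega_rad_s = w,
        re_j_s = Re(jv), im_j_s = Im(jv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("SpectralDensitySet", class(out))
  out
}

#' Serialize a spectral-density set to CSV
#'
#' @param jset A `SpectralDensitySet`.
#' @param path Output path.
#' @export
write_spectral_density <- function(jset, path) {
  utils::write.csv(as.data.frame(jset), path, row.names = FALSE)
  invisible(path)
}

# j value lookup helper
j_lookup <- function(jset, m, mp, omega, what = c("complex", "re")) {
  what <- match.arg(what)
  r <- jset[jset$m == m & jset$mp == mp &
              abs(jset$omega_rad_s - omega) <= 1e-9 * max(1, abs(omega)), ]
  if (nrow(r) == 0) stop("missing (m, mp, omega) entry in spectral-density set")
  if (what == "re") r$re_j_s[1] else complex(real = r$re_j_s[1],
                                             imaginary = r$im_j_s[1])
}

# ---- matrix exponential action (Arnoldi) ----------------------------------

# dense matrix exponential by scaling-and-squaring on a Taylor/Pade-like
# series; H is small (Krylov subspace)
.expm_small <- function(H) {
  nrm <- max(colSums(abs(H)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  A <- H / 2^s
  E <- diag(nrow(H)) + 0i
  term <- E
  for (k in 1:18) {
    term <- term %*% A / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# y ~ exp(-Gamma t) v by Arnoldi approximation with adaptive substepping;
# the local error is estimated from the Krylov residual term
# beta * h_{m+1,m} * |[exp(-H tau)]_{m,1}| and the substep halved until it
# falls below tol * |y| (expokit-style, effective for stiff dissipative
# spectra where the hard components of v die immediately)
expv <- function(op, v, t, m_krylov = 30, tol = 1e-9) {
  if (t == 0) return(v + 0i)
  y <- v + 0i
  remaining <- t
  tau <- t
  while (remaining > 0) {
    beta <- sqrt(sum(Mod(y)^2))
    if (beta == 0) return(y)
    mk <- min(m_krylov, op$dim)
    Vk <- matrix(0i, length(y), mk)
    H <- matrix(0i, mk + 1, mk)
    Vk[, 1] <- y / beta
    actual <- mk
    happy <- FALSE
    for (j in seq_len(mk)) {
      w <- operator_apply(op, Vk[, j])
      for (i in seq_len(j)) {
        H[i, j] <- sum(Conj(Vk[, i]) * w)
        w <- w - H[i, j] * Vk[, i]
      }
      # one re-orthogonalisation pass for stability
      for (i in seq_len(j)) {
        c2 <- sum(Conj(Vk[, i]) * w)
        H[i, j] <- H[i, j] + c2
        w <- w - c2 * Vk[, i]
      }
      nw <- sqrt(sum(Mod(w)^2))
      H[j + 1, j] <- nw
      if (nw < 1e-12 * beta) { actual <- j; happy <- TRUE; break }
      if (j < mk) Vk[, j + 1] <- w / nw
    }
    Hs <- H[seq_len(actual), seq_len(actual), drop = FALSE]
    hlast <- Re(H[actual + 1, actual])
    repeat {
      tau <- min(tau, remaining)
      E <- .expm_small(-Hs * tau)
      err <- if (happy) 0 else beta * hlast * Mod(E[actual, 1]) * tau
      ynew_norm <- beta * sqrt(sum(Mod(E[, 1])^2))
      if (err <= tol * max(ynew_norm, 1e-30 * beta) || tau <= 1e-6 * t) break
      tau <- tau / 2
    }
    y <- beta * as.vector(Vk[, seq_len(actual), drop = FALSE] %*%
                            E[, 1])
    remaining <- remaining - tau
    tau <- tau * 2   # try growing again next substep
  }
  y
}

#' Orientational correlation function under the SFB operator
#'
#' \eqn{G_{m,m'}(t) = \langle v_{k,m'} | e^{-\Gamma t} | v_{k,m}\rangle}
#' (independent of the lab index k); diagonal components start at
#' \eqn{G(0) = 1/5}.
#'
#' @param op An L = 2 [build_operator()] result.
#' @param k Lab index (unused beyond validation; blocks are identical).
#' @param m Body-frame index of the starting vector.
#' @param tgrid Nonnegative, increasing time grid (s).
#' @param mp Body-frame index of the projection vector (default `m`).
#' @return data.frame with columns `t`, `re_G`, `im_G`.
#' @export
correlation_function <- function(op, k = 0, m = 0, tgrid, mp = m) {
  stopifnot(all(tgrid >= 0), !is.unsorted(tgrid))
  v <- starting_vector(op, m) + 0i
  vp <- starting_vector(op, mp)
  out <- data.frame(t = tgrid, re_G = NA_real_, im_G = NA_real_)
  tprev <- 0
  y <- v
  for (r in seq_along(tgrid)) {
    y <- expv(op, y, tgrid[r] - tprev)
    tprev <- tgrid[r]
    g <- sum(vp * y)
    out$re_G[r] <- Re(g); out$im_G[r] <- Im(g)
  }
  out
}

# ---- rigid-rotor closed form (Favro) --------------------------------------

# rank-2 rotational diffusion generator in the m = -2..2 basis
.favro_generator <- function(Dtens) {
  J <- angular_momentum_matrices(2)
  Dtens[1, 1] * J$Jx %*% J$Jx + Dtens[2, 2] * J$Jy %*% J$Jy +
    Dtens[3, 3] * J$Jz %*% J$Jz +
    (Dtens[1, 2] + Dtens[2, 1]) / 2 * (J$Jx %*% J$Jy + J$Jy %*% J$Jx) +
    (Dtens[1, 3] + Dtens[3, 1]) / 2 * (J$Jx %*% J$Jz + J$Jz %*% J$Jx) +
    (Dtens[2, 3] + Dtens[3, 2]) / 2 * (J$Jy %*% J$Jz + J$Jz %*% J$Jy)
}

#' Closed-form rigid-rotor spectral densities (Favro solution)
#'
#' Rank-2 spectral densities of rigid anisotropic rotational diffusion,
#' obtained from the 5 x 5 rotational diffusion generator (for an axial
#' tensor the decay rates are 6 Dperp, 5 Dperp + Dpar, 2 Dperp + 4 Dpar).
#'
#' @param D A [diffusion_tensor()] or a 3 x 3 diffusion matrix (s^-1) in AF
#'   axes.
#' @param omegas Angular frequencies, rad/s.
#' @return A `SpectralDensitySet` (k = kp = 0) with attribute `rates`
#'   holding the five decay rates.
#' @export
favro_rigid <- function(D, omegas) {
  Dm <- if (inherits(D, "DiffusionTensor")) diag(D$values) else as.matrix(D)
  G2 <- .favro_generator(Dm)
  rates <- sort(Re(eigen(G2, only.values = TRUE)$values))
  rows <- list()
  for (w in omegas) {
    Rm <- solve(G2 + 1i * w * diag(5))
    for (m in -2:2) for (mp in -2:2) {
      jv <- Rm[mp + 3, m + 3] / 5
      rows[[length(rows) + 1L]] <- data.frame(
        k = 0, kp = 0, m = m, mp = mp, omega_rad_s = w,
        re_j_s = Re(jv), im_j_s = Im(jv))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rates") <- rates
  class(out) <- c("SpectralDensitySet", class(out))
  out
}

# ---- Brownian-dynamics oracle ---------------------------------------------

# full d^2(beta) as an array [nb, m', m] (m', m = -2..2): vectorized exact
# evaluation of exp(-i beta Jy) through the cached spectral decomposition of
# Jy, so the convention is identical to reduced_d2() by construction
.d2_spectral_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- eigen(angular_momentum_matrices(2)$Jy)
      Cmat <- matrix(0i, 25, 5)
      for (a in 1:5) for (b in 1:5) {
        Cmat[(b - 1) * 5 + a, ] <- e$vectors[a, ] * Conj(e$vectors[b, ])
      }
      cache <<- list(mu = Re(e$values), C = Cmat)
    }
    cache
  }
})

.d2_full <- function(beta) {
  sc <- .d2_spectral_cache()
  E <- exp(-1i * outer(beta, sc$mu))        # nb x 5
  flat <- Re(E %*% t(sc$C))                 # nb x 25, columns (m' , m) pairs
  array(flat, c(length(beta), 5, 5))
}

# quaternion helpers, vectorized over columns (4 x n matrices), q = (w,x,y,z)
.q_mult <- function(a, b) {
  rbind(a[1, ] * b[1, ] - a[2, ] * b[2, ] - a[3, ] * b[3, ] - a[4, ] * b[4, ],
        a[1, ] * b[2, ] + a[2, ] * b[1, ] + a[3, ] * b[4, ] - a[4, ] * b[3, ],
        a[1, ] * b[3, ] - a[2, ] * b[4, ] + a[3, ] * b[1, ] + a[4, ] * b[2, ],
        a[1, ] * b[4, ] + a[2, ] * b[3, ] - a[3, ] * b[2, ] + a[4, ] * b[1, ])
}
.q_conj <- function(q) rbind(q[1, ], -q[2, ], -q[3, ], -q[4, ])

# ZYZ Euler angles from quaternions (active rotation matrix columns)
.q_euler <- function(q) {
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  R13 <- 2 * (x * z + w * y)
  R23 <- 2 * (y * z - w * x)
  R33 <- 1 - 2 * (x^2 + y^2)
  R31 <- 2 * (x * z - w * y)
  R32 <- 2 * (y * z + w * x)
  beta <- acos(pmax(-1, pmin(1, R33)))
  alpha <- atan2(R23, R13)
  gamma <- atan2(R32, -R31)
  deg <- abs(R33) > 1 - 1e-12
  if (any(deg)) {
    R11 <- 1 - 2 * (y^2 + z^2)
    R21 <- 2 * (x * y + w * z)
    a2 <- atan2(R21, R11)
    alpha[deg] <- ifelse(R33[deg] > 0, a2[deg], -a2[deg])
    gamma[deg] <- 0
  }
  list(alpha = alpha, beta = beta, gamma = gamma)
}

#' Brownian/Langevin simulation oracle for orientational correlations
#'
#' Integrates the linear Langevin dynamics of the dimensionless modes with
#' the exact Ornstein-Uhlenbeck update (matrix exponential + stationary
#' noise) and propagates the orientation quaternion with the body-frame
#' angular velocity reconstructed from the modes,
#' \eqn{\omega_p(t) = \sum_i \omega^{int}_{ip} x_i(t)}. Correlation
#' functions are averaged over trajectories (and time origins) using the
#' left-invariance of the rotational dynamics:
#' \eqn{G_{m,m'}(t) = (1/5) E[D^2_{m,m'}(\Omega_0^{-1}\Omega_t)]}.
#'
#' @param params An `SFBParameters` object.
#' @param seed Integer seed (fixed seed: bit-identical trajectories).
#' @param n_traj Number of trajectories.
#' @param dt Time step (s); must satisfy `dt < 0.1 / max rate`.
#' @param t_max Maximum lag time (s).
#' @param stride Steps between stored orientation snapshots.
#' @param components List of `c(m, mp)` pairs to report (default diagonal
#'   m = 0 and m = 2).
#' @param n_origins Time origins per trajectory (variance reduction).
#' @return data.frame with columns `m, mp, t, re_G, im_G, se` (Monte-Carlo
#'   standard error of the real part).
#' @export
bd_oracle <- function(params, seed = 1L, n_traj = 1000L, dt, t_max,
                      stride = 5L, components = list(c(0, 0), c(2, 2)),
                      n_origins = 4L) {
  W <- params$omega_io
  V <- params$omega_int
  N <- params$N
  # the mode update is an exact OU step, so the step-size limit comes from
  # the orientation update only: the body angular velocity magnitude and the
  # relaxation/coupling rates of the modes that feed it
  act <- which(rowSums(abs(V)) > 0)
  rate_max <- max(colSums(abs(V[act, , drop = FALSE])),
                  rowSums(abs(W))[act])
  if (dt >= 0.1 / rate_max)
    stop(sprintf("dt = %.3e too large for max rate %.3e (need dt < %.3e)",
                 dt, rate_max, 0.1 / rate_max))
  E <- as.matrix(Matrix::expm(-W * dt))
  Sig <- diag(N) - E %*% t(E)
  es <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
  S <- es$vectors %*% (t(es$vectors) * sqrt(pmax(es$values, 0)))

  n_steps <- ceiling(t_max / dt)
  n_lag <- floor(n_steps / stride)
  total_steps <- n_steps * n_origins  # snapshots span origins + max lag
  snap_every <- stride
  n_snap <- floor(total_steps / snap_every) + 1L

  with_seed(seed, {
    X <- matrix(stats::rnorm(N * n_traj), N, n_traj)
    q <- rbind(rep(1, n_traj), 0, 0, 0)
    Qs <- array(0, c(4, n_traj, n_snap))
    Qs[, , 1] <- q
    isnap <- 1L
    for (s in seq_len(total_steps)) {
      Xn <- E %*% X + S %*% matrix(stats::rnorm(N * n_traj), N, n_traj)
      om_mid <- crossprod(V, (X + Xn) / 2)   # 3 x n_traj body angular velocity
      th <- sqrt(colSums(om_mid^2)) * dt
      half <- th / 2
      sc <- ifelse(th > 1e-30, sin(half) / pmax(th, 1e-300), 0.5) * dt
      dq <- rbind(cos(half), om_mid[1, ] * sc, om_mid[2, ] * sc,
                  om_mid[3, ] * sc)
      q <- .q_mult(q, dq)
      q <- q / rep(sqrt(colSums(q^2)), each = 4)
      X <- Xn
      if (s %% snap_every == 0L) {
        isnap <- isnap + 1L
        Qs[, , isnap] <- q
      }
    }
    # stationarity self-check: the exact OU update must preserve unit
    # variance of every mode
    vfin <- apply(X, 1, stats::var)
    if (any(abs(vfin - 1) > 10 / sqrt(n_traj)))
      stop("variance drift detected in mode update: reduce dt")
    origin_snaps <- unique(round(seq(1L, n_snap - n_lag,
                                     length.out = n_origins)))
    ncmp <- length(components)
    acc <- array(0i, c(n_traj, n_lag + 1L, ncmp))
    for (o in origin_snaps) {
      q0c <- .q_conj(Qs[, , o])
      for (l in 0:n_lag) {
        qrel <- .q_mult(q0c, Qs[, , o + l])
        eul <- .q_euler(qrel)
        dfull <- .d2_full(eul$beta)
        for (ic in seq_len(ncmp)) {
          m <- components[[ic]][1]; mp <- components[[ic]][2]
          acc[, l + 1L, ic] <- acc[, l + 1L, ic] +
            exp(-1i * m * eul$alpha) * dfull[, m + 3, mp + 3] *
            exp(-1i * mp * eul$gamma)
        }
      }
    }
    acc <- acc / length(origin_snaps) / 5
    out <- list()
    for (ic in seq_len(ncmp)) {
      Gm <- colMeans(acc[, , ic, drop = FALSE][, , 1])
      se <- apply(Re(acc[, , ic, drop = FALSE][, , 1]), 2, stats::sd) /
        sqrt(n_traj)
      out[[ic]] <- data.frame(
        m = components[[ic]][1], mp = components[[ic]][2],
        t = (0:n_lag) * stride * dt, re_G = Re(Gm), im_G = Im(Gm), se = se)
    }
    do.call(rbind, out)
  })
}

# ---- mode reduction and Markovian fast path -------------------------------

#' Reduce an SFB parameter set to its most rotation-coupled modes
#'
#' Internal coordinate/momentum pairs are ranked by the norm of their
#' friction coupling to the angular-momentum block in `omega_io`; the
#' angular-momentum modes are always kept. The retained fraction of total
#' coupling weight is reported in `meta$retained_weight`.
#'
#' @param params An `SFBParameters` object.
#' @param budget Maximum number of modes in the result (>= number of
#'   angular-momentum modes).
#' @return A reduced `SFBParameters`.
#' @export
mode_reduction <- function(params, budget) {
  lab <- params$labels
  iL <- which(lab == "angular-momentum")
  iq <- which(lab == "coordinate")
  ip <- which(lab == "momentum")
  stopifnot(budget >= length(iL))
  if (!length(iq)) return(params)
  W <- params$omega_io
  wgt <- vapply(seq_along(ip), function(kk) {
    sqrt(sum(W[ip[kk], iL]^2) + sum(W[iL, ip[kk]]^2))
  }, numeric(1))
  n_pairs_keep <- max(0L, min(length(iq), (budget - length(iL)) %/% 2L))
  keep <- order(wgt, decreasing = TRUE)[seq_len(n_pairs_keep)]
  keep <- sort(keep)
  retained <- if (sum(wgt) > 0) sum(wgt[keep]) / sum(wgt) else 1
  sel <- c(iq[keep], ip[keep], iL)
  out <- new_sfb_parameters(
    W[sel, sel, drop = FALSE],
    params$omega_int[sel, , drop = FALSE],
    lab[sel], params$temperature,
    meta = c(params$meta, list(retained_weight = retained,
                               reduced_from = params$N)))
  out
}

#' Markovian (adiabatic-elimination) effective diffusion tensor
#'
#' Second-order elimination of all momentum and internal modes yields an
#' effective rotational diffusion tensor
#' \eqn{D_{eff} = \omega^{int T} (\omega^{io})^{-1} \omega^{int}}
#' (symmetrized); for a rigid rotor this is exactly kB T Xi_RR^-1. Used as
#' the fast path: [favro_rigid()] on the result approximates the full
#' solver in the diffusive regime.
#'
#' @param params An `SFBParameters` object.
#' @return 3 x 3 effective diffusion tensor (s^-1, AF axes).
#' @export
markovian_diffusion <- function(params) {
  C <- t(params$omega_int) %*% solve(params$omega_io, params$omega_int)
  (C + t(C)) / 2
}

#' Spectral densities with automatic Hermite convergence
#'
#' Builds the operator at increasing `nu_max` until the maximum relative
#' change of Re j over the requested grid drops below `tol` (default 0.5%).
#'
#' @param params An `SFBParameters` object.
#' @param omegas Angular frequencies, rad/s.
#' @param m,mp Index vectors as in [spectral_density()].
#' @param nu_max Either an integer or `"auto"`.
#' @param tol Relative convergence tolerance for `"auto"`.
#' @param max_dim Operator budget per [build_operator()].
#' @return A `SpectralDensitySet` with attribute `nu_max_used`.
#' @export
sfb_spectral_density <- function(params, omegas, m = -2:2, mp = -2:2,
                                 nu_max = 4, tol = 0.005, max_dim = 20000) {
  if (identical(nu_max, "auto")) {
    nu <- 2L
    prev <- NULL
    repeat {
      op <- build_operator(params, nu_max = nu, L = 2, max_dim = max_dim)
      cur <- spectral_density(op, m = m, mp = mp, omegas = omegas)
      if (!is.null(prev)) {
        scale <- max(abs(prev$re_j_s))
        if (max(abs(cur$re_j_s - prev$re_j_s)) <= tol * scale) break
      }
      prev <- cur
      nu <- nu + 1L
      if (nu > 10L) break
    }
    attr(cur, "nu_max_used") <- nu
    return(cur)
  }
  op <- build_operator(params, nu_max = nu_max, L = 2, max_dim = max_dim)
  out <- spectral_density(op, m = m, mp = mp, omegas = omegas)
  attr(out, "nu_max_used") <- nu_max
  out
}
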