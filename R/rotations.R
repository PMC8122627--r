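# Rank-2 Wigner rotation algebra. Convention: ZYZ active rotations,
# D^L_{k,m}(alpha, beta, gamma) = exp(-i k alpha) d^L_{k,m}(beta) exp(-i m gamma)
# (Brink-Satchler). Matrix rows/columns are indexed m = -L..L throughout.

#' Euler angles (ZYZ, active)
#'
#' @param alpha,beta,gamma Angles in radians; `beta` is folded into `[0, pi]`
#'   and `alpha`, `gamma` into `[0, 2*pi)`.
#' @return Object of class `EulerAngles`.
#' @export
euler_angles <- function(alpha = 0, beta = 0, gamma = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  # fold beta into [0, pi] using d^L symmetries via the rotation matrix
  R <- rot_zyz(alpha, beta, gamma)
  ang <- matrix_to_euler(R)
  structure(list(alpha = ang[1], beta = ang[2], gamma = ang[3]),
            class = "EulerAngles")
}

# 3x3 active rotation matrix Rz(alpha) Ry(beta) Rz(gamma)
rot_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

# Extract (alpha, beta, gamma) in ZYZ active convention from a rotation matrix
matrix_to_euler <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(beta)) < 1e-12) {
    # gimbal: only alpha + sign*gamma defined; put it all in alpha
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha %% (2 * pi), beta, gamma %% (2 * pi))
}

# Angular momentum matrices for rank L in the |L m> basis (m = -L..L),
# standard (space-fixed) commutation [J1, J2] = +i J3.
angular_momentum_matrices <- function(L) {
  m <- seq(-L, L)
  dim_ <- 2 * L + 1
  Jz <- diag(m + 0i)
  cp <- sqrt(L * (L + 1) - m * (m + 1))  # <m+1| J+ |m>
  Jp <- matrix(0i, dim_, dim_)
  for (i in seq_len(dim_ - 1)) Jp[i + 1, i] <- cp[i]
  Jm <- Conj(t(Jp))
  list(Jx = (Jp + Jm) / 2, Jy = (Jp - Jm) / (2i), Jz = Jz)
}

#' Reduced Wigner matrix d^2(beta)
#'
#' Computed as the matrix exponential `exp(-i beta Jy)` in the rank-2
#' representation (real by construction). Rows and columns run over
#' m' , m = -2..2. `d2[m' + 3, m + 3]` is \eqn{d^2_{m',m}(\beta)}.
#'
#' @param beta Rotation angle about y, radians.
#' @return 5 x 5 real matrix.
#' @export
reduced_d2 <- function(beta) {
  stopifnot(is.finite(beta))
  J <- angular_momentum_matrices(2)
  e <- eigen(J$Jy)  # Hermitian; eigen() general path keeps exactness adequate
  d <- e$vectors %*% diag(exp(-1i * beta * e$values)) %*% Conj(t(e$vectors))
  Re(d)
}

# closed-form row d^2_{m,0}(beta) for m = -2..2 (vectorised over beta);
# used as the fast path for probe weights and by the Brownian-dynamics oracle
d2_m0 <- function(beta) {
  cb <- cos(beta); sb <- sin(beta)
  cbind(sqrt(3 / 8) * sb^2,
        sqrt(3 / 2) * sb * cb,
        (3 * cb^2 - 1) / 2,
        -sqrt(3 / 2) * sb * cb,
        sqrt(3 / 8) * sb^2)
}

#' Full rank-2 Wigner rotation matrix D^2(Omega)
#'
#' @param omega An [euler_angles()] object.
#' @return Object of class `WignerBlock`: a list with the 5 x 5 complex
#'   `matrix` (`[k + 3, m + 3]` holding \eqn{D^2_{k,m}}), and `L = 2`.
#' @export
wigner_D2 <- function(omega) {
  stopifnot(inherits(omega, "EulerAngles"))
  m <- seq(-2, 2)
  d <- reduced_d2(omega$beta)
  D <- exp(-1i * m * omega$alpha) * t(exp(-1i * m * omega$gamma) * t(d))
  structure(list(matrix = D, L = 2L, omega = omega), class = "WignerBlock")
}

#' Body-frame angular momentum operator matrices
#'
#' Components of the infinitesimal rotation operator acting on the body
#' (second) index of \eqn{D^L_{k,m}}: right multiplication by the standard
#' J_p matrices. They are Hermitian and obey the anomalous body-fixed
#' commutation \eqn{[M_1, M_2] = -i M_3} (cyclic).
#'
#' @param L Integer rank (default 2).
#' @return List of three (2L+1) x (2L+1) complex matrices `M1`, `M2`, `M3`.
#' @export
body_angular_momentum <- function(L = 2) {
  stopifnot(L >= 0, L == round(L))
  J <- angular_momentum_matrices(L)
  # f(Omega) expanded on D^L_{k,m}: (M_p f) has coefficient matrix c J_p,
  # i.e. the operator matrix acting on the m-index column vector is t(J_p).
  list(M1 = t(J$Jx), M2 = t(J$Jy), M3 = t(J$Jz))
}

#' Euler angles rotating the attached frame into a probe's dipolar frame
#'
#' The dipolar frame z-axis is the C -> H unit vector expressed in the
#' attached frame (AF); the x-axis choice is a gauge and gamma is returned 0.
#'
#' @param structure A [molecular_structure()].
#' @param probe A probe entry `list(C=, H=)` (single H index here).
#' @param af Either `NULL` (AF = input coordinate axes) or a list with
#'   `axes` (3 x 3, columns = AF axes in input coordinates) and `origin`
#'   (Angstrom), as produced by [diffusion_tensor()].
#' @return An [euler_angles()] `Omega_AD` with `gamma = 0`.
#' @export
probe_frame_angles <- function(structure, probe, af = NULL) {
  v <- structure$position[probe$H[1], ] - structure$position[probe$C, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("zero-length C-H vector in probe")
  v <- v / nv
  if (!is.null(af)) v <- as.vector(t(af$axes) %*% v)
  beta <- acos(max(-1, min(1, v[3])))
  alpha <- if (abs(sin(beta)) < 1e-12) 0 else atan2(v[2], v[1])
  euler_angles(alpha, beta, 0)
}
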