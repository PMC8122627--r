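# Synthetic fixtures: toy structures with positive-semidefinite Hessians so
# that the whole pipeline (structure -> friction -> SFB operator -> spectral
# densities -> T1/T2/NOE) is testable without any external input. Spring
# constants default to soft bonds (~30 kcal mol^-1 A^-2) so that internal
# frequencies, angular-momentum relaxation and tumbling are within a few
# decades of each other: this is the regime the Brownian-dynamics oracle can
# integrate accurately, and it is spelled out in the methods vignette.

# Hessian (SI, N/m) of a network of harmonic distance springs at zero tension
spring_hessian <- function(pos_A, springs) {
  n <- nrow(pos_A)
  H <- matrix(0, 3 * n, 3 * n)
  for (s in springs) {
    i <- s$i; j <- s$j
    u <- pos_A[j, ] - pos_A[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- s$k * outer(u, u)
    ii <- 3 * i - 2:0; jj <- 3 * j - 2:0
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic structure + Hessian fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{rigid_rotor}{Six equal beads on the coordinate axes placed so the
#'     inertia tensor matches `I` (kg m^2, 3-vector). Marked rigid: no
#'     internal modes enter the SFB construction; the returned stiff
#'     all-pairs spring Hessian still validates as a minimum.}
#'   \item{bead_pair}{A C-H diatomic at separation `d` (Angstrom) with one
#'     bond spring `k` (kcal mol^-1 A^-2).}
#'   \item{tri_bead}{A C-H-H triangle with bond springs `k_bond` (sides 1-2,
#'     1-3) and `k_angle` (side 2-3); `masses` (u, length 3) overrides the
#'     standard element masses, e.g. for coarse-grained ("extended atom")
#'     beads.}
#'   \item{random_psd}{`n` carbon beads at random non-clashing positions
#'     with a random positive-semidefinite Hessian built as P^T G^T G P in
#'     the mass-weighted Eckart-complement (scale `stiffness`, kcal mol^-1
#'     A^-2).}
#' }
#'
#' @param name One of `"rigid_rotor"`, `"bead_pair"`, `"tri_bead"`,
#'   `"random_psd"`.
#' @param I Inertia principal values (kg m^2), rigid_rotor only.
#' @param k,k_bond,k_angle Spring constants, kcal mol^-1 A^-2.
#' @param d Bond length / triangle side, Angstrom.
#' @param n Atom count, random_psd only.
#' @param stiffness Stiffness scale, random_psd only.
#' @param mass_u Bead mass for rigid_rotor/random_psd, u.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with `structure` ([molecular_structure()]) and `hessian`
#'   ([hessian_matrix()], SI units).
#' @export
make_fixture <- function(name, I = rep(1e-45, 3), k = 30, k_bond = 30,
                         k_angle = 30, d = 1.09, n = 4, stiffness = 30,
                         mass_u = 12.011, masses = NULL, seed = 1L) {
  kconv <- sfb_constants$kcalmol_A2
  ang <- sfb_constants$angstrom
  switch(
    name,
    rigid_rotor = {
      m <- mass_u * sfb_constants$amu
      u3 <- c((-I[1] + I[2] + I[3]) / 2, (I[1] - I[2] + I[3]) / 2,
              (I[1] + I[2] - I[3]) / 2)
      if (any(u3 <= 0))
        stop("requested inertia violates the triangle inequality")
      abc <- sqrt(u3 / (2 * m)) / ang   # Angstrom
      pos <- rbind(c(abc[1], 0, 0), c(-abc[1], 0, 0),
                   c(0, abc[2], 0), c(0, -abc[2], 0),
                   c(0, 0, abc[3]), c(0, 0, -abc[3]))
      st <- molecular_structure(rep("C", 6), pos,
                                mass = rep(mass_u, 6), rigid = TRUE)
      springs <- list()
      for (i in 1:5) for (j in (i + 1):6)
        springs <- c(springs, list(list(i = i, j = j, k = 300 * kconv)))
      list(structure = st,
           hessian = hessian_matrix(spring_hessian(pos * ang, springs),
                                    units = "si"))
    },
    bead_pair = {
      pos <- rbind(c(0, 0, 0), c(0, 0, d))
      st <- molecular_structure(c("C", "H"), pos)
      if (d >= 0.8 && d <= 1.5) st <- add_probe(st, 1, 2)
      H <- spring_hessian(pos * ang, list(list(i = 1, j = 2, k = k * kconv)))
      list(structure = st, hessian = hessian_matrix(H, units = "si"))
    },
    tri_bead = {
      pos <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0))
      st <- molecular_structure(c("C", "H", "H"), pos, mass = masses)
      if (d >= 0.8 && d <= 1.5) st <- add_probe(st, 1, c(2, 3))
      springs <- list(list(i = 1, j = 2, k = k_bond * kconv),
                      list(i = 1, j = 3, k = k_bond * kconv),
                      list(i = 2, j = 3, k = k_angle * kconv))
      list(structure = st,
           hessian = hessian_matrix(spring_hessian(pos * ang, springs),
                                    units = "si"))
    },
    random_psd = {
      if (n < 3) stop("random_psd needs n >= 3")
      with_seed(seed, {
        repeat {
          pos <- matrix(stats::runif(3 * n, -1.5, 1.5), n, 3)
          dm <- as.matrix(stats::dist(pos))
          if (min(dm[upper.tri(dm)]) > 0.8) break
        }
        st <- molecular_structure(rep("C", n), pos, mass = rep(mass_u, n))
        m_kg <- st$mass * sfb_constants$amu
        Rb <- rigid_body_basis(m_kg, pos * ang)
        P <- diag(3 * n) - Rb %*% t(Rb)
        G <- matrix(stats::rnorm(9 * n * n), 3 * n)
        S <- crossprod(G) / (3 * n)
        # mass-weighted PSD target, then back to Cartesian SI
        Hm <- P %*% S %*% P * (stiffness * kconv / mean(m_kg))
        sqm <- rep(sqrt(m_kg), each = 3)
        H <- outer(sqm, sqm) * ((Hm + t(Hm)) / 2)
        list(structure = st, hessian = hessian_matrix(H, units = "si"))
      })
    },
    stop("unknown fixture spec: ", name)
  )
}
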