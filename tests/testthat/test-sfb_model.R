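test_that("internal modes: diatomic closed form and scaling contract", {
  k <- 30
  fx <- make_fixture("bead_pair", k = k, d = 1.09)
  md <- internal_modes(fx$hessian, fx$structure)
  mu <- prod(fx$structure$mass) / sum(fx$structure$mass) * sfb_constants$amu
  expect_equal(md$n_internal, 1L)
  expect_rel_equal(md$omega, sqrt(k * sfb_constants$kcalmol_A2 / mu), 1e-6)
  # mass-weighted eigenvectors orthonormal -> unit equilibrium variance of
  # the dimensionless coordinate by construction
  expect_equal(crossprod(md$U), diag(md$n_internal), tolerance = 1e-10,
               ignore_attr = TRUE)

  rr <- make_fixture("rigid_rotor")
  mdr <- internal_modes(rr$hessian, rr$structure)
  expect_identical(mdr$n_internal, 0L)
})

test_that("build_sfb reduces to the inertial rotor closed form", {
  I <- 1e-45; xi <- 3e-32; Temp <- 298
  par <- sfb_rigid_rotor(rep(I, 3), rep(xi, 3), Temp)
  expect_equal(par$omega_io, diag(rep(xi / I, 3)), tolerance = 1e-12)
  expect_equal(par$omega_int, diag(rep(sqrt(kB * Temp / I), 3)),
               tolerance = 1e-12)

  # geometric route on the octahedral rigid fixture agrees with the direct
  # construction from its own tensors
  rr <- make_fixture("rigid_rotor", I = rep(1e-45, 3))
  fr <- friction_tensor(rr$structure, NULL, Reff = 2, eta = 1.09e-3)
  parg <- build_sfb(rr$structure, rr$hessian, fr, Temp)
  expect_identical(parg$N, 3L)
  Iaf <- parg$meta$inertia_af
  expect_rel_equal(diag(parg$omega_io), diag(fr$Xi_RR) / diag(Iaf), 0.02)
})

test_that("omega_io has streaming/dissipation split with the right scalings", {
  fx <- make_fixture("tri_bead")
  p1 <- fixture_params(fx, eta = 1.0e-3)
  p2 <- fixture_params(fx, eta = 2.0e-3)
  A1 <- (p1$omega_io - t(p1$omega_io)) / 2
  A2 <- (p2$omega_io - t(p2$omega_io)) / 2
  S1 <- (p1$omega_io + t(p1$omega_io)) / 2
  S2 <- (p2$omega_io + t(p2$omega_io)) / 2
  scale <- max(abs(p1$omega_io))
  expect_lt(max(abs(A1 - A2)) / scale, 1e-12)       # eta-independent streaming
  expect_lt(max(abs(S2 - 2 * S1)) / scale, 1e-12)   # dissipation linear in eta
  ev <- eigen(S1, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))              # PSD
  expect_gt(min(Re(eigen(p1$omega_io)$values)), -1e-6 * max(abs(p1$omega_io)))
  # omega_int rows only on angular-momentum modes
  expect_true(all(rowSums(abs(p1$omega_int))[p1$labels != "angular-momentum"]
                  == 0))
  expect_identical(p1$N, 9L)  # 6n - 9 at n = 3
})

test_that("bead_pair q/p block has damped-oscillator eigenvalues", {
  # underdamped regime: stiff spring, small beads
  fx <- make_fixture("bead_pair", k = 300, d = 1.09)
  md <- internal_modes(fx$hessian, fx$structure)
  fr <- friction_tensor(fx$structure, md$A, Reff = 0.5, eta = 1.09e-3)
  par <- build_sfb(fx$structure, fx$hessian, fr, 298)
  iq <- which(par$labels == "coordinate")
  ip <- which(par$labels == "momentum")
  ev <- eigen(par$omega_io[c(iq, ip), c(iq, ip)])$values
  # independent oracle: relative-coordinate Langevin with the series
  # friction of two beads, zeta_r = zeta/2, mass mu
  zeta <- bead_friction(0.5, 1.09e-3)
  mu <- prod(fx$structure$mass) / sum(fx$structure$mass) * sfb_constants$amu
  gam <- (zeta / 2) / mu
  expect_rel_equal(sort(Re(ev)), rep(gam / 2, 2), 1e-6)
  expect_lt(abs(sort(Im(ev))[2] - sqrt(md$omega^2 - (gam / 2)^2)) /
              md$omega, 1e-6)

  # zero-coupling diagnostic removes the rotation-internal block
  par0 <- build_sfb(fx$structure, fx$hessian, fr, 298, zero_coupling = TRUE)
  iL <- which(par0$labels == "angular-momentum")
  expect_true(all(par0$omega_io[ip, iL] == 0))
})

test_that("equilibrium is stationary; broken scaling is detected", {
  fx <- make_fixture("tri_bead")
  par <- fixture_params(fx)
  expect_lt(stationarity_residual(par), 1e-10)
  expect_gt(stationarity_residual(par, variance_scale = 1.5), 1e-4)

  # residual invariant under orthogonal remixing of the (degenerate)
  # coordinate modes and corresponding momentum modes
  th <- 0.4
  R <- diag(par$N)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  R[1:2, 1:2] <- rot; R[4:5, 4:5] <- rot
  par2 <- par
  par2$omega_io <- t(R) %*% par$omega_io %*% R
  par2$omega_int <- t(R) %*% par$omega_int
  expect_lt(stationarity_residual(par2), 1e-10)
})

test_that("single-excitation spectrum of Gamma equals omega_io", {
  fx <- make_fixture("tri_bead")
  par <- fixture_params(fx)
  op <- build_operator(par, nu_max = 2, L = 0)
  single <- which(rowSums(op$basis) == 1L)
  # order single-excitation states by which mode is excited
  ord <- apply(op$basis[single, ], 1, which.max)
  sub <- as.matrix(op$A_re)[single[order(ord)], single[order(ord)]]
  ev_sub <- sort(Mod(eigen(sub, only.values = TRUE)$values))
  ev_io <- sort(Mod(eigen(par$omega_io, only.values = TRUE)$values))
  expect_rel_equal(ev_sub, ev_io, 1e-8)
})

test_that("SFB parameters serialize and restore", {
  fx <- make_fixture("bead_pair")
  par <- fixture_params(fx)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_sfb_parameters(par, tmp)
  got <- read_sfb_parameters(tmp)
  expect_equal(got$omega_io, par$omega_io, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(got$omega_int, par$omega_int, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_identical(got$labels, par$labels)
})
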