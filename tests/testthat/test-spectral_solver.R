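test_that("operator basis counting and structural sparsity", {
  rs <- rigid_sphere_params(ratio = 1e3)
  op1 <- build_operator(rs$params, nu_max = 1)
  expect_identical(op1$dim, 20L)           # (1 ground + 3 single) x 5 m
  op <- build_operator(rs$params, nu_max = 3)
  # no matrix element changes total excitation by 2 or more
  tot <- rowSums(op$basis)
  hi <- (op$i - 1L) %% op$nherm + 1L
  hj <- (op$j - 1L) %% op$nherm + 1L
  expect_true(all(abs(tot[hi] - tot[hj]) <= 1L))
  # m changes by at most 1
  mi <- (op$i - 1L) %/% op$nherm
  mj <- (op$j - 1L) %/% op$nherm
  expect_true(all(abs(mi - mj) <= 1L))
  # equilibrium ground state is annihilated (L = 0 block)
  op0 <- build_operator(rs$params, nu_max = 3, L = 0)
  v0 <- numeric(op0$dim); v0[1] <- 1
  expect_lt(max(Mod(sfbnmr:::operator_apply(op0, v0))), 1e-30)
  expect_error(build_operator(rs$params, nu_max = 6, max_dim = 100),
               "mode_reduction")
})

test_that("rigid sphere in high friction matches the diffusive closed form", {
  rs <- rigid_sphere_params(ratio = 1e3)
  tau <- 1 / (6 * rs$D)
  op <- build_operator(rs$params, nu_max = 4)
  js <- spectral_density(op, m = 0, mp = 0, omegas = c(0, 1 / tau))
  expect_rel_equal(js$re_j_s[1], tau / 5, 0.01)
  expect_rel_equal(js$re_j_s[2], tau / 10, 0.01)
  # high-frequency decay
  jhi <- spectral_density(op, m = 0, mp = 0, omegas = 1e6 / tau)
  expect_lt(abs(jhi$re_j_s), 1e-4 * js$re_j_s[1])
  # off-diagonal components vanish for the isotropic rotor
  joff <- spectral_density(op, m = 2, mp = 0, omegas = 1 / tau)
  expect_lt(abs(joff$re_j_s), 1e-8 * js$re_j_s[1])
  # k-blocks are equivalent; k != k' vanishes identically
  j11 <- spectral_density(op, k = 1, kp = 1, m = 0, mp = 0, omegas = 0)
  expect_equal(j11$re_j_s, js$re_j_s[1], tolerance = 1e-12)
  j10 <- spectral_density(op, k = 1, kp = 0, m = 0, mp = 0, omegas = 0)
  expect_identical(j10$re_j_s, 0)
})

test_that("favro closed form: Lorentzian limit, axial rates, Parseval", {
  D <- 2e10
  fv <- favro_rigid(diag(rep(D, 3)), omegas = c(0, 6 * D))
  tau <- 1 / (6 * D)
  expect_rel_equal(j_lookup(fv, 0, 0, 0, "re"), tau / 5, 1e-10)
  expect_rel_equal(j_lookup(fv, 0, 0, 6 * D, "re"), tau / 10, 1e-10)
  expect_rel_equal(attr(fv, "rates"), rep(6 * D, 5), 1e-10)

  fva <- favro_rigid(diag(c(1, 1, 2) * 1e10), omegas = 0)
  expect_rel_equal(sort(unique(round(attr(fva, "rates") / 1e10, 6))),
                   c(6, 7, 10), 1e-9)

  # (2/pi) integral of Re j = G(0) = 1/5; integrate in the dimensionless
  # variable x = omega/rate so quadrature sees O(1) scales
  rate <- 6e10
  igr <- stats::integrate(function(x) {
    vapply(x, function(xi)
      j_lookup(favro_rigid(diag(c(1, 1.5, 2) * 1e10), xi * rate),
               0, 0, xi * rate, "re") * rate,
      numeric(1))
  }, 0, Inf, rel.tol = 1e-9)
  expect_rel_equal(2 / pi * igr$value, 1 / 5, 1e-6)
})

test_that("correlation functions: initial value, bound, diffusive decay", {
  rs <- rigid_sphere_params(ratio = 1e3)
  tau <- 1 / (6 * rs$D)
  op <- build_operator(rs$params, nu_max = 4)
  tg <- seq(0, 3 * tau, length.out = 16)
  G <- correlation_function(op, m = 0, tgrid = tg)
  expect_equal(G$re_G[1], 0.2, tolerance = 1e-10)
  expect_true(all(abs(G$re_G) <= 0.2 + 1e-10))
  expect_rel_equal(G$re_G, 0.2 * exp(-6 * rs$D * tg), 0.01)

  # flexible fixture: G(0) = 1/5 and bounded
  par <- fixture_params(make_fixture("bead_pair"))
  opf <- build_operator(par, nu_max = 3)
  Gf <- correlation_function(opf, m = 0,
                             tgrid = c(0, 1e-13, 5e-13, 2e-12))
  expect_equal(Gf$re_G[1], 0.2, tolerance = 1e-10)
  expect_true(all(abs(Gf$re_G) <= 0.2 + 1e-10))
})

test_that("time-rescaling covariance: j(omega; s) = j(omega/s)/s", {
  par <- fixture_params(make_fixture("tri_bead"))
  s <- 3.7
  par_s <- par
  par_s$omega_io <- s * par$omega_io
  par_s$omega_int <- s * par$omega_int
  w <- 2e11
  j1 <- spectral_density(build_operator(par, nu_max = 3), m = 0, mp = 0,
                         omegas = w / s)
  j2 <- spectral_density(build_operator(par_s, nu_max = 3), m = 0, mp = 0,
                         omegas = w)
  expect_rel_equal(j2$re_j_s, j1$re_j_s / s, 1e-10)
})

test_that("Hermite truncation is converged at acceptance settings", {
  for (fx in list(make_fixture("bead_pair"), make_fixture("tri_bead"))) {
    par <- fixture_params(fx)
    tau <- 1 / (6 * mean(diag(markovian_diffusion(par))))
    oms <- c(0, 1 / tau)
    j3 <- spectral_density(build_operator(par, nu_max = 3), m = 0, mp = 0,
                           omegas = oms)
    j4 <- spectral_density(build_operator(par, nu_max = 4), m = 0, mp = 0,
                           omegas = oms)
    expect_rel_equal(j4$re_j_s, j3$re_j_s, 0.005)
  }
  par <- fixture_params(make_fixture("tri_bead"))
  ja <- sfb_spectral_density(par, omegas = 0, m = 0, mp = 0, nu_max = "auto")
  expect_true(attr(ja, "nu_max_used") <= 4)
})

test_that("spectral density set round-trips through CSV", {
  rs <- rigid_sphere_params(1e3)
  js <- spectral_density(build_operator(rs$params, nu_max = 2),
                         m = -2:2, mp = -2:2, omegas = c(0, 1e10))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectral_density(js, tmp)
  got <- utils::read.csv(tmp)
  expect_equal(got$re_j_s, js$re_j_s, tolerance = 1e-12)
  expect_named(got, c("k", "kp", "m", "mp", "omega_rad_s", "re_j_s",
                      "im_j_s"))
})

test_that("bd_oracle is deterministic, stationary, and matches favro on the
           rigid rotor", {
  rs <- rigid_sphere_params(ratio = 30)   # diffusive but cheap
  tau <- 1 / (6 * rs$D)
  rate <- rs$xi / rs$I
  dt <- 0.025 / rate
  a <- bd_oracle(rs$params, seed = 5, n_traj = 60, dt = dt, t_max = tau,
                 stride = 10, components = list(c(0, 0)), n_origins = 1)
  b <- bd_oracle(rs$params, seed = 5, n_traj = 60, dt = dt, t_max = tau,
                 stride = 10, components = list(c(0, 0)), n_origins = 1)
  expect_identical(a, b)
  expect_error(bd_oracle(rs$params, seed = 1, n_traj = 10, dt = 10 / rate,
                         t_max = tau), "too large")

  # oracle chain: oracle == reference solver within MC error at moderate
  # damping (where inertial effects are visible and the pure diffusive
  # form would fail); solver == favro_rigid in the high-friction limit is
  # asserted in the rigid-rotor tests above
  bo <- bd_oracle(rs$params, seed = 17, n_traj = 3000, dt = dt,
                  t_max = 2 * tau, stride = 50,
                  components = list(c(0, 0), c(2, 2)), n_origins = 2)
  op <- build_operator(rs$params, nu_max = 5)
  for (cmp in list(c(0, 0), c(2, 2))) {
    bi <- bo[bo$m == cmp[1] & bo$mp == cmp[2], ]
    G <- correlation_function(op, m = cmp[1], tgrid = bi$t, mp = cmp[2])
    z <- abs(bi$re_G - G$re_G) / pmax(bi$se, 1e-15)
    expect_lt(max(z[-1]), 3)
    # and the diffusive form is already a fair (few percent) description
    expect_lt(max(abs(bi$re_G - 0.2 * exp(-6 * rs$D * bi$t))), 0.05 * 0.2)
  }
})

test_that("mode reduction: identity on rigid, rigid-limit on bead_pair,
           converged on tri_bead", {
  rs <- rigid_sphere_params(1e3)
  expect_identical(mode_reduction(rs$params, 3), rs$params)

  # bead_pair internal pair decouples from rotation: dropping it leaves j
  # unchanged at the rigid-rotor value
  par_bp <- fixture_params(make_fixture("bead_pair"))
  red_bp <- mode_reduction(par_bp, budget = 2)
  expect_identical(sum(red_bp$labels == "angular-momentum"), 2L)
  j_full <- spectral_density(build_operator(par_bp, nu_max = 3),
                             m = 0, mp = 0, omegas = 0)
  j_red <- spectral_density(build_operator(red_bp, nu_max = 3),
                            m = 0, mp = 0, omegas = 0)
  expect_rel_equal(j_red$re_j_s, j_full$re_j_s, 1e-6)

  par_tb <- fixture_params(make_fixture("tri_bead"))
  red_tb <- mode_reduction(par_tb, budget = 5)
  expect_gte(red_tb$meta$retained_weight, 0.99)
  jf <- spectral_density(build_operator(par_tb, nu_max = 3), m = 0, mp = 0,
                         omegas = 0)
  jr <- spectral_density(build_operator(red_tb, nu_max = 3), m = 0, mp = 0,
                         omegas = 0)
  expect_rel_equal(jr$re_j_s, jf$re_j_s, 0.02)
})

test_that("Markovian fast path agrees with the reference solver on
           fixtures", {
  for (fx in list(make_fixture("tri_bead"),
                  make_fixture("random_psd", n = 4, seed = 2))) {
    par <- fixture_params(fx)
    Deff <- markovian_diffusion(par)
    tau <- 1 / (6 * mean(diag(Deff)))
    oms <- c(0, 1 / tau, 3 / tau)
    j_ref <- spectral_density(build_operator(par, nu_max = 3), m = 0, mp = 0,
                              omegas = oms)
    j_fast <- favro_rigid(Deff, omegas = oms)   # Deff is in AF axes
    for (i in seq_along(oms)) {
      expect_rel_equal(j_lookup(j_fast, 0, 0, oms[i], "re"),
                       j_ref$re_j_s[i], 0.05)
    }
  }
})
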