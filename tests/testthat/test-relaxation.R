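test_that("assembled J obeys the Wigner weight identities", {
  # rigid isotropic rotor: J is independent of Omega_AD because
  # sum_m d^2_{m,0}(beta)^2 = 1
  rs <- rigid_sphere_params(1e3)
  tau <- 1 / (6 * rs$D)
  op <- build_operator(rs$params, nu_max = 3)
  js <- spectral_density(op, m = -2:2, mp = -2:2, omegas = c(0, 1 / tau))
  set.seed(8)
  for (b in c(0, pi / 2, runif(3, 0.1, 3))) {
    Jt <- assemble_J(js, euler_angles(0.7, b, 0))
    expect_rel_equal(Jt$J[Jt$omega_rad_s == 0], 2 / 5 * tau, 0.011)
  }
  # beta = pi/2 weight vector
  w <- sfbnmr:::d2_m0(pi / 2)
  expect_equal(as.vector(w), c(sqrt(3 / 8), 0, -1 / 2, 0, sqrt(3 / 8)),
               tolerance = 1e-12)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  # beta = 0: only m = 0 survives
  expect_equal(as.vector(sfbnmr:::d2_m0(0)), c(0, 0, 1, 0, 0),
               tolerance = 1e-12)
})

test_that("extreme narrowing limits of the observables", {
  rs <- rigid_sphere_params(ratio = 20, I = 1e-46)   # very fast tumbling
  tau <- 1 / (6 * rs$D)
  w <- probe_frequencies(400)
  expect_lt(max(w) * tau, 0.02)
  op <- build_operator(rs$params, nu_max = 4)
  js <- spectral_density(op, m = -2:2, mp = -2:2, omegas = sort(unique(w)))
  Jt <- assemble_J(js, euler_angles(0, pi / 2, 0))
  res <- relaxation_observables(list(Jt), 400)
  expect_rel_equal(res$T1_ms / res$T2_ms, 1, 0.01)
  gH <- sfb_constants$gamma_H; gC <- sfb_constants$gamma_C
  expect_rel_equal(res$NOE, 1 + gH / (2 * gC), 0.01)
  expect_gt(res$NOE, 1); expect_lte(res$NOE, 1 + gH / (2 * gC) + 1e-6)

  # CH2 with two equivalent protons doubles the rates exactly
  res2 <- relaxation_observables(list(Jt, Jt), 400)
  expect_equal(res2$T1_ms, res$T1_ms / 2, tolerance = 1e-12)
  expect_equal(res2$T2_ms, res$T2_ms / 2, tolerance = 1e-12)
  expect_equal(res2$NOE, res$NOE, tolerance = 1e-12)

  # CSA adds to 1/T1 without touching the dipolar NOE numerator
  res_csa <- relaxation_observables(list(Jt), 400,
                                    csa = list(delta_sigma_ppm = 50, J = Jt))
  expect_lt(res_csa$T1_ms, res$T1_ms)
  expect_lt(res_csa$T2_ms, res$T2_ms)
})

test_that("T1 has a single minimum near wC * tau = 1 on the rigid path", {
  wset <- probe_frequencies(600)
  wC <- wset[["wC"]]
  taus <- 10^seq(-10.5, -7.5, length.out = 25)
  T1 <- vapply(taus, function(tau) {
    fv <- favro_rigid(diag(rep(1 / (6 * tau), 3)), omegas = sort(unique(wset)))
    Jt <- assemble_J(fv, euler_angles(0, pi / 2, 0))
    relaxation_observables(list(Jt), 600)$T1_ms
  }, numeric(1))
  i <- which.min(T1)
  expect_gt(i, 1); expect_lt(i, length(taus))
  expect_true(all(diff(T1[seq_len(i)]) < 0))
  expect_true(all(diff(T1[i:length(taus)]) > 0))
  expect_lt(abs(log10(wC * taus[i])), 0.35)
})

test_that("percentage deviation follows the printed convention", {
  expect_equal(percentage_deviation(440.0, 449.9), 2.3)
  expect_equal(percentage_deviation(402.6, 420.5), 4.4)
  expect_equal(percentage_deviation(100, 100), 0)
  expect_error(percentage_deviation(0, 1), "positive")
})

test_that("deviation_summary aggregates and handles degenerate input", {
  one <- data.frame(observable = "T1", exp = 100, calc = 107)
  rep1 <- deviation_summary(one)
  expect_equal(rep1$summary$mean_e, 7.0)
  expect_equal(rep1$summary$max_e, 7.0)
  expect_equal(rep1$ss, 49, tolerance = 1e-12)

  tab <- data.frame(observable = rep(c("T1", "T2"), each = 2),
                    exp = c(100, 200, 50, NA), calc = c(110, 180, 55, 1))
  rep2 <- deviation_summary(tab)
  expect_equal(rep2$summary$n, c(2L, 1L))
  expect_equal(rep2$summary$mean_e[1], 10.0)
  expect_true(all(rep2$per_entry$e >= 0))
  expect_true(all(rep2$summary$mean_e <= rep2$summary$max_e))
})

test_that("NOE stays in the dipolar window on fixtures", {
  for (ratio in c(50, 1e3)) {
    rs <- rigid_sphere_params(ratio = ratio)
    op <- build_operator(rs$params, nu_max = 3)
    w <- probe_frequencies(600)
    js <- spectral_density(op, m = -2:2, mp = -2:2, omegas = sort(unique(w)))
    Jt <- assemble_J(js, euler_angles(0, pi / 2, 0))
    res <- relaxation_observables(list(Jt), 600)
    expect_gt(res$NOE, 1)
    expect_lte(res$NOE,
               1 + sfb_constants$gamma_H / (2 * sfb_constants$gamma_C) + 1e-9)
    expect_lte(res$T2_ms, res$T1_ms * (1 + 1e-9))
  }
})

test_that("pipeline runs, is deterministic, and T2 falls with viscosity in
           slow tumbling", {
  cfg <- list(fixture = list(name = "tri_bead"), temperature_K = 298,
              viscosity_Pa_s = 1.09e-3, reff_A = 2.0,
              frequencies_MHz = 600, nu_max = 3)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(r1$probe_type[1], "CH2")
  meta <- attr(r1, "meta")
  expect_identical(meta$Reff, 2.0)

  # slow tumbling regime reached by cranking viscosity: T2 monotone down
  cfg$viscosity_Pa_s <- 0.5; cfg$mode_budget <- 3
  rA <- run_pipeline(cfg)
  cfg$viscosity_Pa_s <- 1.0
  rB <- run_pipeline(cfg)
  expect_lt(rB$T2_ms[1], rA$T2_ms[1])

  # config files and result CSV round-trip
  out <- withr::local_tempfile(fileext = ".csv")
  cfgf <- withr::local_tempfile(fileext = ".json")
  cfg2 <- list(fixture = list(name = "tri_bead"), frequencies_MHz = 600,
               nu_max = 2, out = out)
  jsonlite::write_json(cfg2, cfgf, auto_unbox = TRUE)
  res <- run_pipeline(cfgf)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".meta.json")))
  got <- utils::read.csv(out)
  expect_equal(got$T1_ms, res$T1_ms, tolerance = 1e-9)
})

test_that("fit_reff respects bounds and warns at the boundary", {
  cfg <- list(fixture = list(name = "tri_bead"), temperature_K = 298,
              viscosity_Pa_s = 1.09e-3, reff_A = 2.0,
              frequencies_MHz = c(400, 600), nu_max = "auto",
              mode_budget = 3)
  truth <- run_pipeline(cfg)
  exp_tab <- data.frame(probe = truth$probe, freq_MHz = truth$freq_MHz,
                        T1_ms = truth$T1_ms, T2_ms = truth$T2_ms,
                        NOE = truth$NOE)
  expect_warning(
    fit <- fit_reff(cfg, exp_tab, bounds = c(2.5, 3.0), step = 0.1),
    "boundary")
  expect_equal(fit$Reff, 2.5)
  expect_true(fit$at_boundary)
})
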