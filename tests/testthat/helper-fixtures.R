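# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the shipped benchmark table.

kB <- sfb_constants$kB

# rigid spherical rotor parameters in a given damping regime:
# ratio = xi / sqrt(I kB T)
rigid_sphere_params <- function(ratio = 1e3, I = 1e-45, temperature = 298) {
  xi <- ratio * sqrt(I * kB * temperature)
  list(params = sfb_rigid_rotor(rep(I, 3), rep(xi, 3), temperature),
       D = kB * temperature / xi, xi = xi, I = I)
}

# full flexible parameter set from a fixture
fixture_params <- function(fx, Reff = 2.0, eta = 1.09e-3,
                           temperature = 298, ...) {
  md <- internal_modes(fx$hessian, fx$structure)
  fr <- friction_tensor(fx$structure, md$A, Reff = Reff, eta = eta, ...)
  build_sfb(fx$structure, fx$hessian, fr, temperature, modes = md)
}

# random Euler angles under a fixed seed
random_angles <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    euler_angles(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                 stats::runif(1, 0, 2 * pi)))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected),
                                              .Machine$double.xmin)), tol)
}
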