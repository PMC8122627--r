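Package: sfbnmr
Title: Semi-Flexible Brownian Modelling of 13C NMR Spin Relaxation
Version: 0.1.0
Authors@R: person("SFB", "Maintainers", email = "sfbnmr@example.org",
    role = c("aut", "cre"))
Description: Predicts 13C NMR spin-relaxation observables (T1, T2 and the
    heteronuclear NOE) of semi-rigid molecules in solution with the
    semi-flexible Brownian (SFB) stochastic model: a Fokker-Planck
    description of a rotator coupled to N = 6n-9 dissipative harmonic modes
    built from a reference structure, its Hessian and a bead hydrodynamic
    model whose single free parameter is the effective atomic radius Reff.
    Includes the rank-2 Wigner algebra, a sparse Hermite-basis reference
    solver for orientational spectral densities, closed-form rigid-rotor
    (Favro) and Brownian-dynamics simulation oracles, synthetic fixtures,
    deviation statistics against experimental tables and Reff fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
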