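---
title: "The semi-flexible Brownian model behind sfbnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The semi-flexible Brownian model behind sfbnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`sfbnmr` predicts ¹³C spin-relaxation observables — T1, T2 and the
heteronuclear NOE — for semi-rigid molecules tumbling in solution. The
dynamic model is the semi-flexible Brownian (SFB) picture: a rigid-body
rotator coupled to a bath of `N = 6n − 9` dimensionless harmonic modes
built from the `3n − 6` internal coordinates of an `n`-atom molecule, their
conjugate momenta, and the three body-frame angular-momentum components.
The joint density `ρ(Ω, x, t)` of orientation and modes obeys a
Fokker–Planck equation

```
dρ/dt = −Γ ρ,   Γ = Γ0 + Γint,
Γ0   = Σ_ij ω^io_ij  (OU drift of the modes),
Γint = Σ_ip ω^int_ip x_i M_p   (modes feeding the rotation generators),
```

whose stationary state is the standard Gaussian over `x` times the uniform
orientational distribution. Everything NMR-measurable follows from the
rank-2 orientational correlation functions
`G_{m,m'}(t) = ⟨D²*_{k,m}(Ω₀) D²_{k,m'}(Ω_t)⟩` and their Fourier–Laplace
transforms `j_{m,m'}(ω)`, which the package computes with a sparse
resolvent solver in a product basis of Wigner functions and Hermite
(boson) states.

## From structure to operator

1. **Inputs.** A reference (local-minimum) structure in PDB format, its
   Cartesian Hessian (plain text, Tinker units `kcal mol⁻¹ Å⁻²` by
   default), and an experiment descriptor: temperature, solvent viscosity,
   spectrometer ¹H frequency, probe (CH or CH₂), hydrodynamic boundary
   condition, and the effective atomic radius `Reff` — the model's only
   adjustable parameter.
2. **Internal modes.** The mass-weighted Hessian is Eckart-projected
   (3 translations + 3 rotations removed; 5 for linear geometries) and
   diagonalized. Each normal coordinate is scaled by `ω_k/√(kBT)` so its
   equilibrium variance is 1.
3. **Friction.** Every atom is a Stokes bead of radius `Reff`
   (`ζ = 6πηR` stick, `4πηR` slip). The generalized friction tensor is
   `Ξ = Bᵀ Z B`, where `B` maps rotational plus internal mode velocities
   to bead velocities about the centre of diffusion, and rigid translation
   is removed from every column by subtracting the friction-weighted mean
   velocity (the Schur complement of free translation). Free-draining beads
   are the default; a Rotne–Prager pairwise correction is available behind
   `hydrodynamic_interaction = "rotne_prager"`. Per-bead rotational
   friction (`8πηR³`) is neglected against the translational lever-arm
   terms, as is standard for bead models.
4. **Attached frame.** The AF is the principal frame of the rotational
   diffusion tensor `D = kBT Ξ_RR⁻¹`, centred at the centre of diffusion,
   `z` along the smallest-friction axis, with deterministic sign fixing.
   This makes the rotational block of the drift diagonal and is the
   conventional choice in this model family; the choice is recorded in the
   output metadata.
5. **Drift and coupling.** In the dimensionless variables
   `x = (q̃, p̃, L̃)` with `L̃ = (kBT)^{-1/2} I^{-1/2} L`, Hamiltonian
   streaming couples each `q̃_k ↔ p̃_k` antisymmetrically at `ω_k`,
   dissipation acts on the momentum and angular-momentum blocks through
   `Ξ` (so the symmetric part of `ω^io` is positive semidefinite and
   scales linearly with viscosity), and `ω^int = √(kBT) I^{-1/2}` feeds
   the body-frame rotation generators. Second-order precession terms are
   dropped.

## Numerical choices

* **Discretization.** `Γ0` becomes the number-quadratic boson form
  `Σ ω^io_ij b_i†b_j`; `Γint` multiplies `x_i = b_i + b_i†` by the rank-2
  body-frame generators and carries the `−i` of a streaming
  (anti-Hermitian) term. The basis is truncated at total Hermite
  excitation `ν_max` (default 4; `nu_max = "auto"` doubles until the
  spectral densities move by less than 0.5%). On all shipped fixtures
  `ν_max = 2–3` is already converged to better than 0.1%.
* **Resolvent solves.** `j(ω) = ⟨v_{m'} |(iω + Γ)⁻¹| v_m⟩` with
  equilibrium-weighted Wigner starting vectors (`G(0) = 1/5`), solved as a
  doubled real sparse system by a sparse LU factorization shared across the
  five starting vectors.
* **Correlation functions.** Matrix-exponential action by an Arnoldi
  (Krylov) scheme with local error control; the stiff overdamped components
  of the operator die out immediately, so steps are limited by accuracy on
  the slow orientational dynamics only.
* **Spectrometer mapping.** `J(ω) = 2 Re Σ D²*_{m0}(Ω_AD) D²_{m'0}(Ω_AD)
  j_{m,m'}(ω)` (rigid-isotropic form `(2/5)τ/(1+ω²τ²)`), then the standard
  ¹³C–¹H dipolar expressions at `{0, ω_C, ω_H−ω_C, ω_H, ω_H+ω_C}`. CH₂
  probes add the two protons' rates with their individual geometries;
  dipole–dipole cross-correlation is neglected. An axial CSA term is
  implemented but off by default because published applications do not
  state the anisotropy used. The C–H bond length defaults to 1.09 Å;
  absolute T1 scales as `r⁶`, so override `r_CH_A` deliberately.
* **Ties and degeneracies.** Eigenvector signs are fixed by making the
  largest-magnitude component positive; axis ordering is by diffusion
  eigenvalue with `y = z × x` enforcing right-handedness; degenerate modes
  are orthonormalized deterministically. Linear geometries (`n = 2` or a
  vanishing inertia eigenvalue) drop the axial angular-momentum mode:
  `N = 2(3n−5) + 2`.

## Design choices where the problem was open

* **Inertia reference point.** Friction is referenced to the centre of
  diffusion; the inertia tensor entering `L̃` is taken about the same
  point, so the angular-momentum variable is defined consistently. For
  equal beads the centre of diffusion coincides with the centroid and the
  distinction vanishes; the residual mismatch with the centre-of-mass
  kinetic reference is second order in their separation and is absorbed by
  the calibrated `Reff`.
* **Mode construction.** Any construction yielding a stationary Gaussian,
  the spin-boson single-excitation spectrum equal to `ω^io`, and the
  rigid-rotor and diffusive limits is conformant; the linearized
  phase-space Langevin route above is the one implemented, and those
  contracts are what the test suite enforces.
* **Fast path.** Adiabatic elimination of all momentum and internal modes
  gives an effective diffusion tensor
  `D_eff = ω^intᵀ (ω^io)⁻¹ ω^int` (exactly `kBT Ξ_RR⁻¹` for a rigid
  body); `favro_rigid()` on `D_eff` is the Markovian approximation and is
  required to agree with the reference solver within 5% on fixtures.
* **Reff fitting.** A 0.1 Å grid search minimizing the summed squared
  percentage deviations over all observables, frequencies and probes, with
  ties broken toward the smaller radius. The grid step matches the
  precision at which optimal radii are reported in the benchmark tables.
* **Deviation convention.** `e = 100·|calc − exp|/exp`, rounded half away
  from zero to one decimal. The shipped benchmark tables reproduce the
  published aggregate means (8.5/5.8/7.7) exactly under this convention;
  a few printed cells differ by 0.1 because they were derived from
  unrounded calculated values, so per-cell comparisons allow ±0.1.

## What the synthetic fixtures emulate — and what they do not

The fixtures (`rigid_rotor`, `bead_pair`, `tri_bead`, `random_psd`)
reproduce the *structure* of the real problem: positive semidefinite
Hessians with exact rigid-body null spaces, bead friction with
internal–rotational coupling (present whenever masses and frictions are
weighted differently, e.g. the C–H–H triangle), and realistic solvent
conditions (298 K, `η = 1.09×10⁻³ Pa s`, `Reff = 2 Å` — the rule-of-thumb
starting radius). Bond springs default to 30 kcal mol⁻¹ Å⁻² — softer than
real C–H stretches — so that internal, angular-momentum and tumbling time
scales sit within a few decades of each other and the Brownian-dynamics
oracle can integrate the orientation accurately; the oracle-equivalence
fixture additionally uses coarse-grained bead masses (24/12/12 u) for the
same reason. Consequently a green suite establishes the correctness of the
operator algebra, the hydrodynamics, the limits and the observable mapping
— it does not certify absolute agreement with any published oligosaccharide
value, which would require the original force-field Hessians (external
inputs by design). A qualitative expectation for a user-supplied saccharide
Hessian with `Reff ≈ 2 Å` is agreement with experiment within a factor of
about two, improving to 5–20% after fitting `Reff`.

## Known limitations

* Harmonic internal dynamics only: bistable torsional surfaces (common for
  glycosidic linkages) are outside the model and were the dominant error
  source in the published benchmark.
* Dipolar (plus optional axial CSA) relaxation only; no cross-correlated
  rates, no ¹⁵N/²H observables.
* Free-draining hydrodynamics by default; interacting-bead corrections are
  approximate and their error is absorbed into the fitted `Reff`.
* The reference solver is exact but dense in the Hermite excitation; for
  large `N` use `mode_reduction()` (coupling-ranked truncation, retained
  weight reported) or the Markovian fast path.
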