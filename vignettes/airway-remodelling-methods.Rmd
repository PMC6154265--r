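---
title: "Methods: a mechanochemical morphoelastic airway model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanochemical morphoelastic airway model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(airwaymorph)
```

## The model in brief

`airwaymorph` couples three sub-models on a common Lagrangian material
grid of a two-layer airway cylinder (inner collagen-only subepithelial
basement membrane, outer smooth-muscle-dominated layer):

1. **Quasi-static nonlinear elasticity.** The grown, stress-free
   configuration ξ(R, t) deforms incompressibly in plane strain,
   r² = r₁² + ξ² − ξ₁². The mixture strain energy is the
   volume-fraction-weighted sum of constituent energies: every solid phase
   contributes a neo-Hookean ground matrix, and the contractile and ECM
   phases add two symmetric helical fibre families at angle α from the
   circumferential direction with energy
   (k₁/2k₂)[exp(k₂(I₄ − I₄⁰)²) − 1] per family, where I₄ is the squared
   fibre stretch and the offset I₄⁰ is 1 for muscle and λ_u² for collagen
   (crimped fibres recruit only beyond the recruitment stretch λ_u; both
   fibre terms are tension-gated). Active stress is a Hill function of
   local agonist concentration, split equally over the two families, so
   the full force density Φ_c·A_c(k) acts along the fibre directions.
   Radial momentum balance is solved by shooting on the deformed inner
   radius.
2. **Stimulus dynamics.** Challenges are a normalised Gaussian train
   f(t). Global inflammation μ and the nodal agonist field k follow
   linear clearance ODEs with source terms; tensile fibre stress τ
   releases additional agonist at rate a_c (the mechanotransductive
   feedback). k is a material field riding the grid — no diffusion or
   explicit advection, which is exact for a pure advection–reaction
   system in the Lagrangian frame.
3. **Growth.** Constituent balances with inflammation-tiered and
   stress-modulated rates produce net solid mass; at constant hydration
   Φ_w = 0.70 this dilates the mixture and, with the outer radius pinned,
   drives inward growth. The simulation starts at the closed-form
   homeostatic steady state, which is a genuine fixed point of the
   discrete update (see below).

Assumptions inherited from this model family: axisymmetry with no
torsion or buckling, zero axial growth and displacement, a single shared
deformation for all solid constituents (constrained mixture), stress
arising from the elastic deformation only (no residual stress from
growth), and quasi-static mechanics (growth is slow compared with
elastic equilibration).

## Parameters

Units: stresses and pressures in kPa, lengths in mm, time in days, agonist
concentration in arbitrary units (the agonist level is effectively
non-dimensional). All parameter containers validate their invariants at
construction.

**Geometry.** R₁ = 1.8 mm (a bovine-scale airway, comparable to a
generation-4 human airway), R_int = 1.95 mm (SBM thickness ~0.15 mm, at
the histological scale of remodelled human airways), R₂ = 2.3 mm.

**Material** (`material_params()`): ground stiffness c_ground = 4 kPa
shared by the contractile and ECM phases (one parameter, chosen for
parsimony and identifiability over a per-phase split), c_neo = 4 kPa for
the proliferative phase, fibre coefficients (k1_c, k2_c) = (2, 1) and
(k1_e, k2_e) = (8, 3), recruitment stretch λ_u = 1.3, fibre angle
α = 5° (nearly circumferential muscle), T_c = 20 kPa, K_d = 0.5,
n = 2. The passive set was chosen so the simulated quasi-static inflation
curve reproduces the compliant-then-stiffening character of published
bovine airway data — inner-radius stretch ≈ 1.5 over 0–2 kPa with
collagen recruiting mid-range — because that data shape is what the
passive-fitting module is designed to consume.

**Turnover rates** (`rate_params()`): c_pc = 1, c_p0 = 0.1,
c_c0 = 0.06 /day, with the apoptosis coefficient defaulted so the
homeostatic contractile fraction is Φ_c* = 0.12; the fixed-point algebra
then gives Φ_p* = 0.008 and the baseline ECM deposition rate c_e0 is
re-solved so Φ_e* = 0.172 closes the 0.30 solid fraction exactly (the
constructor does this and the partition is asserted in tests). The
inflammation tiers are c_c1 = 0.1, c_c2 = 0.2 /day and
c_e1 = 2c_e0, c_e2 = 4c_e0, with thresholds μ₁ = 0.5, μ₂ = 1.5. Two
constraints shaped these choices: the sweep surfaces should show graded
remodelling with a sharp threshold and a closure corner rather than
near-universal closure, and — because the SBM-thickening variant reuses
the outer-layer ECM rates in the inner layer — mild-tier deposition must
exceed the inner layer's degradation balance point c_de(1 − Φ_w), which
requires the tier multiplier to exceed (1 − Φ_w)/Φ_e*. Raising Φ_e* to
0.172 (well within the histological range for airway walls) satisfies
this without inflating the deposition multipliers, which would over-drive
outer-layer ECM growth. Stress modulation defaults: c_cp_f = 0.05
/(day·kPa) on switching (tensile mode), c_p_f = 0 on proliferation; both
gates are selectable between tension and compression, and in compressive
mode the stress magnitude is used so the added rate is non-negative.

**Stimuli** (`stimulus_params()`): a_μ = a_k = 1, c_dμ = c_dk = 1 /day,
a_kμ = 0.1, a_c = 0.01. Challenges default to every 2 days (ω = 0.5/day)
from day 1 within a 50-day window, σ = 0.5 day, shape constant d = 1 (so
each peak integrates to 1; d duplicates σ's role and is kept only as a
configuration knob), horizon 1000 days.

## Numerical choices

* **Lagrangian growth update.** On material points the constituent
  balance reduces to dΦ_a/dt = S_a − Φ_a q and dξ/dt = v, eliminating the
  advective term, satisfying the zero-flux boundary conditions
  identically, and — under forward Euler — preserving the solid-fraction
  sum *exactly* at every step (the discrete sum update has the same fixed
  point as the continuous one). This is why the homeostatic state shows
  zero drift over the full horizon and conservation holds to machine
  precision.
* **Stimulus steps.** μ and k use the exact exponential decay factor with
  trapezoidal treatment of the forcing: pure decay is integrated exactly
  (the tests assert the analytic half-life), non-negativity is structural,
  and the discrete fixed point under constant forcing carries only an
  O((c·dt)²/12) quadrature bias.
* **Equilibrium shooting.** The Lagrange multiplier cancels in
  T_θθ − T_rr, so the outer-boundary residual is a single transmural
  integral, evaluated with piecewise-parabolic (fourth-order) quadrature
  whose weights are precomputed per grid; the root in r₁ is bracketed
  (warm-started from the previous step) and polished by `uniroot` to
  1e-12 mm. Stress profiles and the multiplier are recovered afterwards
  by cumulative quadrature. A soft tube inflated past its limit pressure
  has no equilibrium; the solver reports this as a typed error with the
  bracket residuals.
* **Heaviside conventions.** All threshold gates use H(0) = 0 (strict
  inequality): inflammation tiers, tensile agonist release, and fibre
  recruitment/tension gating.
* **Extra-stress convention.** The constant ground-matrix hydrostatic
  term is absorbed into the Lagrange multiplier so the unstrained
  reference returns exactly zero components; only stress differences are
  mechanically meaningful and those are verified against central finite
  differences of an independently coded strain energy.
* **Closure.** The inward growth velocity diverges as the lumen vanishes
  (v ~ 1/ξ), so a run stops and is flagged `closed` as soon as the next
  step would take the grown inner radius below the closure threshold
  (0.01 mm); sweep surfaces mask closed runs as discarded.
* **Time step.** dt = 0.05 day by default. Convergence is first-order in
  dt because the inflammation level crosses tier thresholds (the duration
  spent above a threshold is resolved to O(dt)); at the default step,
  halving dt and doubling the grid changes the day-55 remodelled radius
  by well under 0.5%, which the suite asserts. Grid resolution (101
  nodes/layer default) is essentially converged at 41 nodes/layer for the
  outcome metrics, so tests and sweeps use 41-node grids and dt = 0.1 day
  with shortened horizons (120 days rather than 1000) where only the
  challenge window and early resolution period matter; the homeostasis
  check runs the full 1000 days at default resolution.
* **Resolution time.** The cross-sectional agonist total uses the
  area-weighted measure ∫k·2πξ dξ over both layers of the grown annulus
  (a radial-integral alternative is provided), with the same parabolic
  quadrature as the mechanics so a nodally linear field integrates
  exactly. The threshold crossing is located by log-linear interpolation
  between stored samples, which is exact for exponential decay. Censored
  runs never receive a numeric resolution time.

## Passive-parameter fitting and the synthetic generator

`generate_synthetic_pr()` emulates a quasi-static pressure–radius
inflation experiment: the forward passive curve (homeostatic composition,
no agonist, ungrown geometry) plus seeded Gaussian noise proportional to
the radius. It stands in for published bovine inflation data, which is
not bundled; it reproduces the smooth monotone compliant-then-stiffening
curve shape but none of a real experiment's systematic features
(hysteresis, adaptation between cycles, measurement drift), so recovery
results demonstrate estimator correctness, not robustness to real-world
artefacts.

`fit_passive_params()` is Levenberg–Marquardt least squares with box
constraints (mirroring the standard curve-fitting workflow for such
data). The default free subset is (c_ground, k1_e): the low-pressure
compliance and the post-recruitment stiffening amplitude, the two moduli
an inflation curve determines well. The exponents and recruitment
stretch are fixed because amplitude/shape pairs of exponential fibre
laws are classically sloppy (a 1%-noise, 20-point curve cannot pin both
k1_e and k2_e); c_neo multiplies the ~1% proliferative fraction and is
structurally unidentifiable from inflation data; and T_c is an active
parameter, set from active-response behaviour rather than fitted. At 1%
radius noise and 20 points, individual replicate estimates scatter at
the Fisher-information level of several percent; the acceptance check
therefore evaluates the Monte-Carlo mean over 50 seeded replicates
(bias, which vanishes with the noise) together with the mean R².

## Design choices that were genuinely open

* **Two-family active stress.** The active dyad is averaged over the two
  symmetric helical families, so the total active force density along
  fibres is Φ_c A_c, the configuration is torsion-free, and the
  fibre-direction stress reduces to Φ_c A_c (cos⁴α + sin⁴α) in the
  homogeneous, pressure-free limit.
* **Reported remodelling outcome.** The remodelled inner radius is
  reported in the grown (unloaded, agonist-free) configuration ξ₁, which
  isolates tissue growth from reversible constriction; the loaded radius
  is also emitted.
* **Periodic protocols.** A frequency ω expands to events t₁ + (i−1)/ω
  within the challenge window, starting at day 1.
* **SBM-thickening variant.** A boolean enables ECM turnover in the inner
  layer using the outer layer's deposition and degradation rates; the
  inner layer has no smooth muscle, so only the ECM balance operates
  there.

## Limitations

No SBM buckling or non-axisymmetric deformation (compressive hoop stress
is reported, not acted on geometrically); no epithelium as an explicit
phase; no circumferential or axial growth, hence no growth-induced
residual stress; no agonist or cytokine diffusion; constituents share one
reference configuration; challenge timing is deterministic. Tier-threshold
crossings make outcomes first-order sensitive to dt near regime
boundaries — sweep thresholds are sharp by design, so grid points adjacent
to a threshold are the least certain. The parameter set is a
self-consistent calibration around the homeostatic partition, not a fit
to longitudinal remodelling data; qualitative regime structure
(thresholds, feedback loops, recovery after challenges) is the intended
output, not patient-scale prediction.
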