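# airwaymorph

Mechanochemical, morphoelastic simulation of long-term asthmatic airway
remodelling.

Asthmatic airways thicken over years of repeated inflammatory episodes and
bronchoconstriction, but it is unclear how much of that remodelling is
driven by inflammation itself and how much by the mechanical stresses that
contraction generates. `airwaymorph` is for researchers in airway
biomechanics and mechanobiology who want to simulate that coupling: it
models the airway wall as a two-layer, growing, nonlinear-elastic cylinder
whose tissue composition evolves under inflammatory and contractile-agonist
challenges, with the fibre-direction stress feeding back on the biology.

## The model

The wall is a constrained mixture of contractile airway smooth muscle
cells (volume fraction Φ_c), proliferative ASMCs (Φ_p), collagen-dominated
ECM (Φ_e) and fluid (Φ_w = 0.70, constant), in an inner collagen-only
layer (the subepithelial basement membrane, SBM) and an outer muscle
layer. Growth is radial and inward: a stress-free grown configuration
ξ(R, t) evolves from the reference radii (R₁ = 1.8 mm, R_int = 1.95 mm,
R₂ = 2.3 mm with ξ₂ pinned at R₂), and an incompressible plane-strain
elastic deformation r(ξ) with r² = r₁² + ξ² − ξ₁² loads it.

* **Mechanics.** Cauchy stress T = −p**1** + T_passive + T_active, with
  Ψ = Σ Φ_a W_a; each phase has a neo-Hookean ground matrix and the
  contractile/ECM phases carry two symmetric helical fibre families with
  exponential stiffening energies, ECM fibres recruiting only above the
  stretch λ_u. Active tone is Hill-type, A_c = T_c k^n/(K_d + k^n), along
  the fibre directions. Radial equilibrium ∂T_rr/∂r + (T_rr − T_θθ)/r = 0
  is solved quasi-statically by shooting on r₁ under T_rr(r₁) = −P₁,
  T_rr(r₂) = −P₂. The mechanotransduction signal is the fibre-direction
  stress τ = T_θθ cos²α + T_zz sin²α.
* **Stimuli.** Challenges are a train of Gaussian peaks f(t). Global
  inflammation obeys dμ/dt = a_μ f − c_dμ μ; the local agonist field obeys
  dk/dt = a_k f − c_dk k + a_kμ μ + a_c τ H(τ) on material points (only
  tensile τ releases agonist).
* **Growth.** Volume fractions follow advection–reaction balances with
  sources: phenotype switching c_cp(μ, τ) (inflammation-tiered plus
  stress-modulated), switch-back c_pc, logistic apoptosis c_a Φ_c²,
  proliferation c_p(τ), and ECM deposition c_be(μ)/degradation c_de. Net
  production dilates the mixture, (1/ξ)∂(ξv)/∂ξ = ΣS_a/(1 − Φ_w), with
  v(ξ₂) = 0, and the simulation starts at the closed-form homeostatic
  steady state Φ*.

A simulation runs 1000 days with challenges confined to the first 50, and
reports the remodelled inner radius 5 days after the final challenge and
the agonist resolution time (days until the cross-sectional agonist total
falls below 1e-6). Two-parameter sweeps reproduce the threshold ("switch")
behaviour of remodelling in challenge frequency, clearance rates,
hyper-responsiveness T_c and mechanotransduction rates.

## Worked example

A coarse inflammation-only experiment (120 simulated days, challenges
every 2 days for 50 days):

```r
library(airwaymorph)

cfg <- simulation_config(
  geometry = grown_geometry(n_inner = 41, n_outer = 41),
  protocol = challenge_protocol(horizon = 120),
  dt = 0.1, store_every = 5L
)
sim <- run_simulation(cfg)
glance(sim)
#>   remodelled_radius_mm loaded_radius_mm resolution_days censored
#> 1                1.413            1.411           16.82    FALSE
#>   final_wall_thickness_mm peak_mu closed aborted
#> 1                  0.6192  0.5836  FALSE   FALSE
```

The airway narrows from 1.8 mm to 1.41 mm (grown, unloaded configuration)
at 5 days after the final challenge — inward wall thickening driven by
inflammation-induced phenotype switching — and partially recovers
afterwards; the wall has thickened from 0.50 to 0.62 mm by day 120. The
agonist clears 16.8 days after the last challenge (`censored` would be
`TRUE` if a mechanotransductive feedback loop kept releasing agonist
indefinitely, as happens at high `T_c`). Peak inflammation 0.58 sits in
the "mild" tier (μ₁ = 0.5 < μ < μ₂ = 1.5). `tidy(sim)` returns the full
time series, `autoplot(sim)` plots it, and `parameter_sweep()` maps
outcome surfaces over any two parameters.

Passive material parameters can be fitted to quasi-static pressure–radius
inflation data (and recovered from synthetic data):

```r
dat <- generate_synthetic_pr(seq(0, 2, length.out = 20),
                             noise_sd = 0.01, seed = 1)
fit <- fit_passive_params(dat, start = c(c_ground = 5.5, k1_e = 5))
glance(fit)$r.squared   # ~0.99
```

A command-line front end over the same functions is installed at
`inst/cli/airwaymorph.R` (`run`, `sweep`, `pr-curve` subcommands, JSON
configs, CSV outputs).

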