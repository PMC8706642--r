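# granupbm

Population-balance simulation of **bi-component high-shear wet granulation**
for formulations that mix a hydrophobic drug substance (e.g. ibuprofen) with
a hydrophilic excipient (e.g. microcrystalline cellulose). The package is
aimed at pharmaceutical process modellers who need to predict not just the
granule size distribution but also granule porosity, liquid content and
**content uniformity** — how evenly the drug ends up distributed across
granule size classes — as functions of the drug fraction of the formulation.

## The model

Granules are tracked by a three-coordinate number density
`F(s1, s2, p)` — drug solid volume, excipient solid volume, pore volume —
with lumped external/internal binder liquid (`le`, `li`) per cell, on a
geometric volume grid (31.5 µm – 6 mm sphere-equivalent diameter).
Mechanisms:

* **Formulation-dependent nucleation.** Spray drops immerse into the powder
  bed with probability `P_im(f1)` (a pluggable, monotonically decreasing
  provider anchored at `P_im(0.5) = 0.67`), forming saturated nuclei at
  critical packing `v_im = v_d (1 + (1−φ_cp)/φ_cp)`, `φ_cp = 0.2`; otherwise
  the drop is coated by hydrophobic drug powder into a "liquid marble"
  (solid-spread nucleus) of diameter `d_d + 2 d_p`, tracked as a separate
  class.
* **Aggregation** with kernel `β = β₀ β*`, where the collision efficiency
  `β* = min(1, (W_c + W_d)/E_k)` compares capillary + viscous bridge work
  against the pair kinetic energy `½ m e_coag² v_r²`; relative velocities
  come from the granular temperature (`Θ ∝ γ² d²`). Merged granule volume
  interpolates between pore-volume-conserving (soft, `ζ = 1 − e_coag → 1`)
  and surface-area-conserving (hard, `ζ → 0`) collisions.
* **Marble-driven surface growth** onto granules larger than the marble's
  rupture spread `D_max = D (1 + 0.12 We)`, **excipient layering** onto wet
  surfaces, **rewetting**, **consolidation**
  (`Δε = k_con U (ε − ε_min)` with internal-liquid squeeze at saturation)
  and optional shear-driven **breakage**.
* **Numerics:** moment-conserving cell-average redistribution, explicit
  Euler with CFL-bounded adaptive steps, and exact conservation ledgers for
  drug, excipient and binder volume (closure ≤ 1e-9 relative is asserted in
  the tests).

Analysis utilities compute d10/d50/d90, per-size-class drug content, the
demixing potential `DP% = (100/x̄) √(Σ w (x − x̄)²)`, and perturbation
sensitivities `(Y₀ − Yᵢ)/Y₀`. A fixtures module generates synthetic
"experiments" (noisy cumulative size distributions and content tables) and
`pareto_fit()` estimates the six tunable constants
(β₀, e_s1, e_s2, k_con, k_layer, k_sg) by two-objective weighted-sum
scalarization with a derivative-free search.

## Worked example

```r
library(granupbm)

cfg <- granulation_config(
  materials = material_set(f1 = 0.5),            # 50% ibuprofen / 50% MCC
  process  = process_conditions(charge_mass = 0.5, q_spray = 2e-5, t_end = 30),
  numerics = list(n_bins = 8L, record_every = 10)
)
rec <- run_simulation(cfg)
rec
#> <granulation_record> 300 steps to t = 30.0 s | d50 = 931 um | DP = 6.86% | max audit err 3.1e-15

glance(rec)[, c("d50", "avg_porosity_vol", "avg_liquid_frac_vol", "dp_percent")]
#>            d50 avg_porosity_vol avg_liquid_frac_vol dp_percent
#> 1 0.0009307293        0.1151643           0.4530991   6.856265

size_class_table(rec$final_state, cfg$materials)
#>       d_lo    d_hi        w     x
#> 1 0.000435 0.00092 4.70e-01 0.496
#> 2 0.000920 0.00195 5.25e-01 0.521
#> 3 0.001948 0.00412 4.65e-03 0.986
#> 4 0.004124     Inf 9.57e-05 0.999
```

Fifteen seconds of liquid addition and fifteen of wet massing turn the 0.5 kg
blend into granules with a volume-median diameter of 931 µm, 11.5% average
porosity and 45% liquid by volume (the 0.6 liquid-to-solid mass ratio makes
very wet granules). The content table shows each diameter class's mass
fraction `w` and its drug mass fraction of solids `x`: the small population
of large granules is drug-rich (they grew by collecting pure-drug marble
shells), and the spread of `x` across classes gives the demixing potential
of 6.9%. `tidy(rec)` returns the full time series; `autoplot(rec)` and
`plot_csd(rec)` draw the standard figures.

Sensitivity scan and closed-loop calibration:

```r
sens <- sensitivity_scan(cfg, outputs = "d50")            # ±10/20% on 6 constants
fx   <- make_fixture(cfg, noise_sd = 0)                   # synthetic experiment
fit  <- pareto_fit(fx, n_weights = 3)                     # Pareto estimation
glance(fit)
```

A thin command-line wrapper lives at `inst/cli/granupbm.R`
(`simulate`, `sensitivity`, `make-fixtures`, `calibrate` subcommands).

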