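---
title: "A bi-component population balance model of high-shear wet granulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bi-component population balance model of high-shear wet granulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

granupbm simulates high-shear wet granulation of a two-solid formulation — a
hydrophobic drug substance (e.g. ibuprofen) and a hydrophilic excipient (e.g.
microcrystalline cellulose) — bound by a sprayed liquid. Its purpose is to
predict, as functions of the drug mass fraction `f1`, the granule size
distribution, porosity, liquid fraction and the *content uniformity* of the
product: how evenly the drug distributes across granule size classes.

## State variables and discretization

Each granule is described by three internal coordinates — drug solid volume
`s1`, excipient solid volume `s2` and pore volume `p` — plus lumped liquid:
all granules in a cell share the same average external (surface) liquid `le`
and internal (pore) liquid `li`. Derived properties follow from the total
volume `v = s1 + s2 + le + p`: sphere-equivalent area `a = pi^(1/3) (6v)^(2/3)`,
porosity `eps = p/v`, and drug content `q = s1/v`.

The number density `F(s1, s2, p)` lives on a geometric grid per coordinate.
Two grid modes exist: `fixed_ratio_4`, a fixed volume ratio of 4 between
bins, and the default `fit_span` mode in which the ratio is chosen so that
the bins span exactly 31.5 µm to 6000 µm sphere-equivalent diameter. The
fixed-ratio-4 law cannot reach 6 mm from 31.5 µm in 20 bins (it overshoots
by two orders of magnitude), so the span — the physically meaningful window
— is honoured by default. A zero node is prepended to every coordinate so granules may carry
exactly none of a component. The 20 bins are applied *per coordinate*,
consistent with the triple integrals of the aggregation terms.

Particles created between nodes are placed by a cell-average
(two-moment) rule: per coordinate the bracketing nodes receive fractions
that conserve both number and first moment exactly; the three-coordinate
split is the tensor product. Attached liquid follows the number fractions.
Targets beyond the grid are clamped to the boundary and the volume
discrepancy is accumulated in a signed overflow ledger, so the global
balances close to round-off at every step; the simulator warns when the
ledger exceeds 0.1% of the solid inventory.

## Rate processes

**Nucleation.** Spray drops (monodisperse, volume `v_d`) either immerse into
the powder bed or are coated by hydrophobic drug powder into "liquid
marbles". The immersion probability `P_im(f1)` is a pluggable provider; the
default is a logistic curve, decreasing in the drug fraction, anchored at
`P_im(0.4) = 0.95` (marble formation essentially absent) and
`P_im(0.5) = 0.67`. Immersion nuclei form instantaneously at critical
packing: `v_im = v_d (1 + (1-phi_cp)/phi_cp)` with `phi_cp = 0.2`, solids
drawn at the current bed composition (mass fractions converted to volume
fractions through the true densities), pores equal to the drop volume and
fully saturated (`li = p = v_d`). Marbles form a separate scalar class
`Fss` with geometry `D = d_d + 2 d_p`; their shell is pure drug. The drop
supply is split between nucleation and granule rewetting by the remaining
un-granulated powder fraction (`f_bed`), decaying as the bed is consumed —
this prevents double-counting binder between the nucleation and rewetting
laws, which the rate equations would otherwise both draw from the full spray
rate. One bookkeeping choice matters for closure: the marble mass draw uses
the full shell volume (`N_ss rho_s1 v_ss_s1`) rather than multiplying by
`f1`; with the multiplier the drawn mass would not equal the marble drug
content and the drug balance could not close.

**Rewetting and layering.** During liquid addition, the non-nucleating spray
fraction deposits on granule surfaces proportionally to each cell's share of
`F v`. Wet granules (`le > 0`) then capture excipient fines at
`ds2/dt = k_layer a Ms2 / rho_s2`; the reservoir depletes mass-consistently.

**Marble-driven surface growth.** A marble rupturing against a granule
spreads its drug shell and drop onto the surface. Rupture requires the
impact to flatten the marble past its maximum spread
`D_max = D (1 + 0.12 We)`, `We = rho_l v_r^2 D / sigma`; only granules at
least that large grow. The growth law is
`ds1/dt = k_sg v^(2/3) Fss` — proportional to marble availability, a
collision-frequency form in the spirit of two-class population balances.
(A per-granule law without the `Fss` factor, at the calibrated
`k_sg = 4.59e-11`, is numerically inert at any defensible unit reading and
would disable the solid-spread pathway entirely; the chosen form is
self-limiting — the total drug delivered can never exceed the marble
reservoir. The *amount* delivered is thus reservoir-set, but the *timing
and recipients* of delivery still depend on `k_sg`, so the sensitivity
scan finds `d50` responding to `k_sg` at the sub-percent level even though
the total marble volume converted does not change.) Each consumed marble
credits its drop volume to the receiving cell's surface liquid.

**Aggregation.** The kernel is `beta = beta0 beta*`, with the collision
efficiency `beta*` the ratio of liquid-bridge work to kinetic energy,
clipped to `[0, 1]`: `beta* = min(1, (Wc + Wd)/Ek)`. The dissipative work is
`Wd = (3 pi mu dtilde^2 e_coag v_r / 4) ln(h/h_a)` with `h` the mean binder
layer thickness `le/a` of the pair and `h_a` the asperity height (dry pairs,
`h <= h_a`, form no bridge and never stick). The capillary work scales the
viscous work by a formulation-dependent capillary number, log-linear in the
pair's drug solid fraction. The kinetic energy is
`Ek = m e_coag^2 v_r^2 / 2` with `m` the reduced (harmonic-mean) mass and
the pair restitution `e_coag = e_A e_B`, each granule's `e` the
mass-weighted mean of its constituents' (pores count as restitution 0 with
zero mass). Relative velocities come from the granular temperature,
`Theta = (5 pi/96) gamma^2 d^2 g(phi_p)`, `v_r = sqrt(32 Theta / pi)`; the
grouping of the volume-fraction factor varies between formulations of the
granular-temperature closure, so
`g(phi_p) = 1/(12 phi_p^2 (1 - phi_p))` is exposed as a configurable
closure — every qualitative property depends only on `Theta ~ gamma^2 d^2`.

Colliding granules merge with additive solids; the new volume interpolates
between the deformation-driven extreme (`zeta = 1`: volume, hence pore
volume, conserved) and the sticking extreme (`zeta = 0`: surface area
conserved): `v = zeta (vA + vB) + (1 - zeta)(aA + aB)^(3/2)/(6 sqrt(pi))`,
where `zeta = 1 - e_coag` is the pair deformability. (Interpolating in area space mixes `a` and `a^(3/2)` terms dimensionally;
the volume form used here reproduces both extremes exactly.) Part of the external
liquid is drawn into the merged pore network by a geometric-mean transfer
with overlap caps; pores close the volume balance subject to `p >= li`.
Population rates follow the standard pairwise double loop with the 1/2
factor and `F(F-1)/2` self-pair correction; marble-marble aggregation
deposits merged marbles into the granule distribution.

**Consolidation.** Collisions compact granules:
`d(eps) = k_con U (eps - eps_min) dt` while `eps > eps_min`, with `U` the
granular-temperature velocity at the cell's size (the collision velocity is
otherwise undefined). The pore volume is re-closed from the new porosity;
when the shrinking pores saturate, internal liquid is squeezed to the
surface (`li = p`). Note the compaction law as implemented means a larger
`k_con` compacts *more* (so granules shrink); the sensitivity harness
reports whichever direction the model actually produces rather than
assuming a sign.

**Breakage.** A shear-proportional binary breakage
(`K = P_brk gamma d`, composition-preserving daughters) is included but
default-off (`P_brk = 0`): its constants are system-specific, user-supplied
inputs, and the headline behaviours here are growth-dominated.

## Numerics

First-order explicit Euler with adaptive steps bounded by a CFL-type rule:
no cell may lose more than `safety` (default 0.5) of its occupants per step,
and the marble class and powder reservoirs are bounded the same way
(`dt_max = 0.1` s, `dt_min = 1e-5` s). All rates are evaluated at the
step-start state and applied synchronously; reservoir draws are rescaled,
never extrapolated, so no inventory goes negative, and the binder drawdown
is computed from the liquid actually deposited, which is what lets the
binder balance close to 1e-6 even across the squeeze and marble pathways.
Oracle comparisons against the analytic constant-kernel decay use
`safety = 0.05`, which holds the Euler error under 2% over two half-lives.
The forward model contains no randomness: identical configurations give
bit-identical records.

## Reference study conditions

The calibrated constants are `beta0 = 4.34e-10` (per pair per s),
`e_s1 = 0.162` (ibuprofen), `e_s2 = 0.07` (MCC), `k_con = 1.67e-3`,
`k_layer = 2.01e-8`, `k_sg = 4.59e-11`, with `phi_cp = 0.2` and a
liquid-to-solid mass ratio of 0.6. The operating-condition defaults describe a realistic lab-scale high-shear
run, chosen once: 2 kg charge, spray 2e-5 m³/s (60 s liquid addition then wet
massing to 120 s), drop diameter 0.4 mm, shear rate 1000 1/s, particle
volume fraction 0.3, ibuprofen primaries 50 µm (USP grade is coarse), MCC
primaries 65 µm, water-like binder (`mu` = 1 mPa s, `sigma` = 0.07 N/m).
The capillary-number regression is a per-formulation input; the default
anchors (`Ca(0.2) = 0.5`, `Ca(0.8) = 2`) make capillary adhesion strengthen
with drug fraction — the direction required for the kernel's composition
dependence to contribute to the observed growth of granules with drug
fraction.

Tests and the acceptance script run scaled-down versions of these
conditions (0.25–1 kg charge, 7–16 bins per coordinate, 16–75 s of process
time); the physics and all calibrated constants are unchanged. The 12-bin
grid keeps a full conservation-audited run around a minute; the 7-bin,
34-second configuration used for closed-loop calibration keeps a single
forward solve under a second so that a six-parameter Nelder–Mead fit
(with simplex restarts; rate constants in log space, restitutions in logit
space, bounds by penalty) completes in minutes.

## What the synthetic fixtures do and do not show

`make_fixture()` emulates a granulation experiment's two measurement tables
— a cumulative size distribution and a per-size-class drug content table —
by running the forward model at known parameters and adding multiplicative
Gaussian noise (re-monotonized, clipped to [0, 1]). Calibration against
such fixtures demonstrates *parameter recovery*: that the estimation
machinery can find generating parameters from the model's own output. It
cannot demonstrate that the model describes any real granulator; real data
carry structural error (drop size distributions, spatial inhomogeneity,
attrition, drying) that the generator deliberately omits. With two
noiseless fixtures (40% and 60% drug), the aggregation and consolidation
constants are recovered well; the layering constant and the excipient
restitution are weakly identified — their influence on the observables at
these conditions is at or below the discretization level, consistent with
the sensitivity ranking.

## Known limitations

* The drug content offset between blend and granules (`dq`, `dq_solid`)
  reflects which powder remains un-granulated. Because marbles capture pure
  drug while immersion nuclei draw at the bed composition, granules at high
  drug fractions finish slightly drug-enriched; measurements that show the
  opposite convergence would implicate mechanisms (preferential exclusion
  of hydrophobic fines from immersion nuclei, strong excipient layering)
  that are inert at the calibrated constants.
* Monodisperse drops; no drying, attrition or spatial compartments.
* Breakage defaults off and its constants are user-supplied.
* Consolidation treats the squeeze threshold as pore saturation; no
  partially-saturated sub-model.
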