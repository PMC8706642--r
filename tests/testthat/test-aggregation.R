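test_that("pair restitution is mass-weighted with inert pores", {
  mats <- material_set(e_s1 = 0.162, e_s2 = 0.07)
  # pure-drug granules on both sides
  A <- granule_tuple(s1 = 1e-12, s2 = 0, p = 2e-13)
  rp <- restitution_pair(A, A, mats)
  expect_equal(rp$e_coag, 0.162^2)
  expect_equal(rp$zeta, 1 - 0.026244, tolerance = 1e-9)
  # equal-mass drug/excipient granule: arithmetic mean of the coefficients
  B <- granule_tuple(s1 = 1e-12, s2 = 1e-12 * mats$rho_s1 / mats$rho_s2, p = 0)
  rpB <- restitution_pair(B, B, mats)
  expect_equal(rpB$e_A, (0.162 + 0.07) / 2, tolerance = 1e-12)
  # fully elastic materials give zero deformability
  me <- material_set(e_s1 = 1, e_s2 = 1)
  expect_equal(restitution_pair(A, A, me)$zeta, 0)
  expect_error(restitution_pair(granule_tuple(0, 0, 1e-12), A, mats),
               class = "granupbm_invalid_pair")
})

test_that("granular-temperature velocity scales linearly in shear rate and size", {
  v1 <- granular_velocity(100, 1e-3, 0.3)
  expect_equal(granular_velocity(200, 1e-3, 0.3), 2 * v1, tolerance = 1e-12)
  expect_equal(granular_velocity(100, 2e-3, 0.3), 2 * v1, tolerance = 1e-12)
  # scalar re-evaluation oracle
  theta <- (5 * pi / 96) * 100^2 * (1e-3)^2 / (12 * 0.3^2 * 0.7)
  expect_equal(v1, sqrt(32 * theta / pi), tolerance = 1e-12)
  expect_error(granular_velocity(100, 1e-3, 1.2),
               class = "granupbm_invalid_parameter")
})

test_that("dissipative work vanishes without a bridge and follows the formula", {
  expect_equal(dissipative_work(1e-3, 0.01, 0.5, 1, h = 1e-6, h_a = 1e-6), 0)
  expect_equal(dissipative_work(1e-3, 0.01, 0.5, 1, h = 0, h_a = 1e-6), 0)
  wd <- dissipative_work(1e-3, 0.01, 0.5, 2, h = 5e-6, h_a = 1e-6)
  expect_equal(wd, 3 * pi * 0.01 * 1e-6 * 0.5 * 2 / 4 * log(5), tolerance = 1e-12)
})

test_that("capillary work scales the viscous reference by the regression", {
  ca <- capillary_number_model(f = c(0.2, 0.8), ca = c(0.5, 2))
  expect_equal(ca(0.2), 0.5, tolerance = 1e-12)   # anchors reproduced exactly
  expect_equal(ca(0.8), 2, tolerance = 1e-12)
  expect_equal(capillary_work(0.5, ca, 3e-9), ca(0.5) * 3e-9)
  one <- function(f) rep_len(1, length(f))
  expect_equal(capillary_work(0.3, one, 7e-10), 7e-10)
  zero <- function(f) rep_len(0, length(f))
  expect_equal(capillary_work(0.3, zero, 7e-10), 0)
})

test_that("collision efficiency is a clipped work-to-energy ratio", {
  cfg <- small_config()
  dry <- granule_tuple(s1 = 1e-11, s2 = 1e-11, p = 2e-12)
  expect_equal(collision_efficiency(dry, dry, cfg), 0)   # no bridge, no sticking
  wet <- granule_tuple(s1 = 1e-11, s2 = 1e-11, p = 2e-12, le = 5e-12)
  bs <- collision_efficiency(wet, wet, cfg)
  expect_gte(bs, 0)
  expect_lte(bs, 1)
  # scalar oracle for the unclipped branch
  mats <- cfg$materials
  der <- granupbm:::tuple_derived(wet, mats)
  v_r <- granular_velocity(cfg$process$gamma, der$d, cfg$process$phi_p)
  e_coag <- der$e^2
  h <- der$le / der$a  # identical granules
  wd <- dissipative_work(der$d, mats$mu, e_coag, v_r, h, mats$h_a)
  wc <- capillary_work(2 * wet$s1 / (2 * wet$s1 + 2 * wet$s2), cfg$capillary, wd)
  ek <- 0.5 * der$mass * e_coag^2 * v_r^2
  expect_equal(bs, min(1, (wc + wd) / ek), tolerance = 1e-9)
  # forced-constant override
  cfg1 <- small_config(kernel_override = "constant")
  expect_equal(collision_efficiency(dry, dry, cfg1), 1)
})

test_that("combination extremes conserve pore volume (soft) or area (hard)", {
  v <- 4e-12
  A <- granule_tuple(s1 = v / 2, s2 = v / 4, p = v / 4)
  # zeta = 1, dry: fully plastic merge conserves total and pore volume
  m1 <- combine_granules(A, A, zeta = 1)
  expect_equal(m1$v, 2 * (A$s1 + A$s2 + A$p), tolerance = 1e-12)
  expect_equal(m1$p, 2 * A$p, tolerance = 1e-12)
  # zeta = 0, equal spheres: area conserved, v_new = 2^(3/2) v
  m0 <- combine_granules(A, A, zeta = 0)
  expect_equal(m0$v, 2^(3 / 2) * v, tolerance = 1e-12)
  expect_equal(surface_area(m0$v), 2 * surface_area(v), tolerance = 1e-9)
  # solids additive, extra void becomes pores
  expect_equal(m0$s1 + m0$s2, 2 * (A$s1 + A$s2))
  expect_gt(m0$p, 2 * A$p)
  # symmetry in the pair
  B <- granule_tuple(s1 = 1e-12, s2 = 3e-12, p = 5e-13, le = 2e-13, li = 1e-13)
  mab <- combine_granules(A, B, 0.6)
  mba <- combine_granules(B, A, 0.6)
  expect_equal(mab, mba, tolerance = 1e-12)
  expect_error(combine_granules(A, B, 1.5), class = "granupbm_invalid_parameter")
})

test_that("external-to-internal liquid transfer needs liquid on both granules", {
  A <- granule_tuple(s1 = 1e-12, s2 = 1e-12, p = 5e-13, le = 4e-13)
  B <- granule_tuple(s1 = 1e-12, s2 = 1e-12, p = 5e-13, le = 0)
  m <- combine_granules(A, B, 0.9)
  expect_equal(m$li, 0)                       # no transfer when one side is dry
  expect_equal(m$le, A$le)                    # external liquid just carried over
  m2 <- combine_granules(A, A, 0.9)
  expect_gte(m2$li, 0)
  expect_gt(m2$li, 0)                         # both wet: some liquid drawn in
  expect_equal(m2$le + m2$li, 2 * A$le, tolerance = 1e-15)
})

test_that("aggregation rates match a brute-force two-cell enumeration", {
  cfg <- small_config(kernel_override = "constant")
  beta0 <- cfg$kinetics$beta0
  st <- micro_state(list(
    list(i = 2, j = 3, k = 1, n = 1000),
    list(i = 2, j = 5, k = 1, n = 400)
  ), cfg)
  props <- granupbm:::cell_properties(st, cfg$materials)
  agg <- granupbm:::aggregation_rates(st, props, cfg)
  # pair rates: self pairs F(F-1)/2, cross pairs F_A F_B, beta* = 1
  r11 <- beta0 * 1000 * 999 / 2
  r12 <- beta0 * 1000 * 400
  r22 <- beta0 * 400 * 399 / 2
  expect_equal(sort(agg$form$rate), sort(c(r11, r12, r22)))
  # depletion: each event removes one partner from each participating cell
  expect_equal(agg$dep_n[1], 2 * r11 + r12)
  expect_equal(agg$dep_n[2], 2 * r22 + r12)
  # formation conserves solid volume pairwise
  sol <- props$s1 + props$s2
  expect_equal(sum(agg$form$rate * (agg$form$s1 + agg$form$s2)),
               r11 * 2 * sol[1] + r22 * 2 * sol[2] + r12 * (sol[1] + sol[2]),
               tolerance = 1e-12)
  # beta0 = 0 switches aggregation off entirely
  cfg0 <- small_config(kinetics = list(beta0 = 0))
  agg0 <- granupbm:::aggregation_rates(st, props, cfg0)
  expect_null(agg0$form)
  expect_null(agg0$dep_n)
})

test_that("aggregation conserves solids and liquid per step in a full run", {
  rec <- run_simulation(small_config())
  expect_lt(max(rec$series$err_api), 1e-9)
  expect_lt(max(rec$series$err_excipient), 1e-9)
  expect_lt(max(rec$series$err_binder), 1e-6)
})
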