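test_that("the logistic immersion-probability provider hits its anchors and decreases", {
  p <- nucleation_probability_provider()
  expect_equal(nucleation_probability(0.5, p), 0.67, tolerance = 1e-10)
  expect_equal(nucleation_probability(0.4, p), 0.95, tolerance = 1e-10)
  # monotone decreasing in the drug fraction
  expect_true(nucleation_probability(0.4, p) > nucleation_probability(0.5, p))
  expect_true(nucleation_probability(0.5, p) > nucleation_probability(0.6, p))

  pc <- nucleation_probability_provider("constant", value = 1)
  expect_equal(nucleation_probability(c(0.1, 0.5, 0.9), pc), c(1, 1, 1))

  pt <- nucleation_probability_provider(
    "table", anchors = data.frame(f1 = c(0.3, 0.6), p_im = c(0.9, 0.2)))
  expect_equal(nucleation_probability(0.45, pt), 0.55, tolerance = 1e-12)

  expect_error(nucleation_probability_provider("constant", value = 1.2),
               class = "granupbm_invalid_parameter")
  expect_error(nucleation_probability(1.2, p),
               class = "granupbm_invalid_parameter")
})

test_that("immersion nucleus volumes follow the critical-packing relation", {
  nv <- immersion_nucleus_volumes(1, 0.2)
  expect_equal(nv$v_im, 5)
  expect_equal(nv$v_im_s, 4)
  # limit: drop fills the nucleus completely
  nv1 <- immersion_nucleus_volumes(2, 0.999999)
  expect_equal(nv1$v_im, 2, tolerance = 1e-5)
  expect_equal(nv1$v_im_s, 0, tolerance = 1e-5)
  # algebraic identity v_im - v_im_s = v_d for any packing fraction
  for (phi in c(0.05, 0.2, 0.5, 0.95)) {
    nv <- immersion_nucleus_volumes(3.7, phi)
    expect_equal(nv$v_im - nv$v_im_s, 3.7, tolerance = 1e-12)
  }
  expect_error(immersion_nucleus_volumes(1, 1.5),
               class = "granupbm_invalid_parameter")
})

test_that("solid-spread marble geometry matches direct sphere arithmetic", {
  ss <- solid_spread_nucleus(d_d = 100e-6, d_p = 10e-6)
  expect_equal(ss$d_ss, 120e-6)
  expect_equal(ss$v_ss, pi / 6 * (120e-6)^3, tolerance = 1e-15)
  expect_equal(ss$v_ss_s1, pi / 6 * ((120e-6)^3 - (100e-6)^3), tolerance = 1e-15)
  # bare drop limit
  ss0 <- solid_spread_nucleus(d_d = 100e-6, d_p = 0)
  expect_equal(ss0$v_ss_s1, 0)
})

test_that("a nucleation-only run reproduces the closed-form drop bookkeeping", {
  p_im <- 0.67
  cfg <- granulation_config(
    materials = material_set(f1 = 0.5),
    process = process_conditions(charge_mass = 2, ls_ratio = 0.06,
                                 q_spray = 2e-5, t_end = 8),
    numerics = list(n_bins = 8L, record_every = 12),
    kinetics = list(beta0 = 0, k_con = 0, k_layer = 0, k_sg = 0),
    nucleation = nucleation_probability_provider("constant", value = p_im),
    spray_split = "all_nucleation"
  )
  rec <- run_simulation(cfg)
  st <- rec$final_state
  v_d <- cfg$process$v_d
  v_sprayed <- st$binder_total   # spray finishes inside t_end
  expect_equal(st$liquid_remaining, 0)
  n_drops <- v_sprayed / v_d

  # drops partition exactly between the two nucleus classes
  expect_equal(sum(st$F), p_im * n_drops, tolerance = 1e-9)
  expect_equal(st$Fss, (1 - p_im) * n_drops, tolerance = 1e-9)

  # total granule volume equals N_im * v_im (solids + drop-sized pores)
  nv <- immersion_nucleus_volumes(v_d, cfg$materials$phi_cp)
  u <- st$grid$nodes
  nn <- length(u)
  vol <- sum(st$F * (rep(u, nn^2) + rep(rep(u, each = nn), nn) +
                       rep(u, each = nn^2))) + sum(st$Le)
  expect_equal(vol, p_im * n_drops * nv$v_im, tolerance = 1e-9)

  # immersion nuclei are born saturated: all their binder is internal
  expect_equal(sum(st$Li), p_im * n_drops * v_d, tolerance = 1e-9)
  expect_equal(sum(st$Le), 0)

  # reservoir draws follow the volume-fraction split of the bed: with
  # immersion only, draws proportional to the volume fractions leave the
  # bed's volume ratio invariant, so the cumulative draw ratio equals the
  # initial split exactly
  mats <- cfg$materials
  cfg_im <- granulation_config(
    materials = cfg$materials, process = cfg$process,
    numerics = list(n_bins = 8L, record_every = 12),
    kinetics = list(beta0 = 0, k_con = 0, k_layer = 0, k_sg = 0),
    nucleation = nucleation_probability_provider("constant", value = 1),
    spray_split = "all_nucleation"
  )
  sti <- run_simulation(cfg_im)$final_state
  drawn1 <- mats$f1 * cfg$process$charge_mass - sti$Ms1
  drawn2 <- (1 - mats$f1) * cfg$process$charge_mass - sti$Ms2
  fv1_0 <- (mats$f1 / mats$rho_s1) /
    (mats$f1 / mats$rho_s1 + (1 - mats$f1) / mats$rho_s2)
  expect_equal((drawn1 / mats$rho_s1) / (drawn2 / mats$rho_s2),
               fv1_0 / (1 - fv1_0), tolerance = 1e-9)

  # binder balance across classes closes
  aud <- audit_state(st, cfg)
  expect_lt(aud$err_binder, 1e-9)
  expect_lt(aud$err_api, 1e-9)
})
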