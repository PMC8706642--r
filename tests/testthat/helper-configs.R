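# Reduced-size study configurations used across the suite. Problem sizes are
# scaled down from the reference conditions (see the methods vignette); the
# physics and the calibrated constants are unchanged.

# generic small run: 0.5 kg charge, 15 s spray + 15 s wet massing, 8 bins
small_config <- function(f1 = 0.5, ...) {
  granulation_config(
    materials = material_set(f1 = f1),
    process = process_conditions(charge_mass = 0.5, q_spray = 2e-5,
                                 t_end = 30),
    numerics = list(n_bins = 8L, record_every = 10),
    ...
  )
}

# conservation audit run: 12 bins per coordinate, 60 s
conservation_config <- function(f1 = 0.5) {
  granulation_config(
    materials = material_set(f1 = f1),
    process = process_conditions(charge_mass = 1, q_spray = 2e-5, t_end = 60),
    numerics = list(n_bins = 12L, record_every = 5)
  )
}

# formulation-trend run: 30 s spray + 45 s wet massing, 12 bins
trend_config <- function(f1) {
  granulation_config(
    materials = material_set(f1 = f1),
    process = process_conditions(charge_mass = 1, q_spray = 2e-5, t_end = 75),
    numerics = list(n_bins = 12L, record_every = 25)
  )
}

# sensitivity-scan run: long enough that the marble reservoir fully converts
sensitivity_config <- function(f1 = 0.5) {
  granulation_config(
    materials = material_set(f1 = f1),
    process = process_conditions(charge_mass = 0.5, q_spray = 2e-5,
                                 t_end = 45),
    numerics = list(n_bins = 8L, record_every = 45)
  )
}

# calibration run: smallest config on which the six constants still act
calibration_config <- function(f1 = 0.5) {
  granulation_config(
    materials = material_set(f1 = f1),
    process = process_conditions(charge_mass = 0.25, q_spray = 2e-5,
                                 t_end = 16),
    numerics = list(n_bins = 7L, record_every = 1000, dt_max = 0.2)
  )
}

table2_params <- function() {
  list(beta0 = 4.34e-10, e_s1 = 0.162, e_s2 = 0.07,
       k_con = 1.67e-3, k_layer = 2.01e-8, k_sg = 4.59e-11)
}

# a dry two-component state with hand-placed cells, for micro-ensemble tests
micro_state <- function(cells, config = small_config()) {
  st <- new_granulation_state(config)
  st$Ms1 <- 0
  st$Ms2 <- 0
  st$liquid_remaining <- 0
  for (cl in cells) {
    st$F[cl$i + 1L, cl$j + 1L, cl$k + 1L] <- cl$n
    if (!is.null(cl$le)) st$Le[cl$i + 1L, cl$j + 1L, cl$k + 1L] <- cl$le
    if (!is.null(cl$li)) st$Li[cl$i + 1L, cl$j + 1L, cl$k + 1L] <- cl$li
  }
  st
}
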