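#' Granule size statistics
#'
#' Volume-weighted cumulative size distribution over sphere-equivalent
#' diameter, with `d10`/`d50`/`d90` obtained by monotone linear interpolation
#' of the cumulative curve.
#'
#' @param state A `granulation_state` (or a `granulation_record`, whose final
#'   state is used).
#' @param materials Optional [material_set()]; defaults are fine since only
#'   geometry enters.
#' @return A list with `curve` (tibble `diameter`, `cum_vol_frac`) and `d10`,
#'   `d50`, `d90` (m).
#' @export
size_statistics <- function(state, materials = material_set()) {
  if (inherits(state, "granulation_record")) state <- state$final_state
  props <- cell_properties(state, materials, floor_frac = 0)
  if (is.null(props)) {
    abort("size statistics are undefined for an empty ensemble",
          class = "granupbm_undefined_statistics")
  }
  ord <- order(props$d)
  d <- props$d[ord]
  w <- (props$n * props$v)[ord]
  cum <- cumsum(w) / sum(w)
  # collapse duplicate diameters, keep the curve strictly increasing in d
  keep <- !duplicated(d, fromLast = TRUE)
  d <- d[keep]
  cum <- cum[keep]
  qd <- function(q) {
    if (length(d) == 1 || q <= cum[1]) return(d[1])
    approx(cum, d, xout = q, rule = 2, ties = "ordered")$y
  }
  list(curve = tibble(diameter = d, cum_vol_frac = cum),
       d10 = qd(0.10), d50 = qd(0.50), d90 = qd(0.90))
}

#' Per-size-class granule content table
#'
#' Collapses the ensemble over (excipient, pore) onto diameter classes (the
#' grid's diameter bins by default) and reports each class's granule weight
#' fraction and drug mass fraction of the granule solids.
#'
#' @param state A `granulation_state`.
#' @param materials A [material_set()] (densities for the mass basis).
#' @param breaks Optional diameter class boundaries (m); defaults to the
#'   grid's bin-edge diameters.
#' @return A tibble with `d_lo`, `d_hi`, `w` (granule mass fraction, summing
#'   to 1) and `x` (drug mass fraction of the class solids).
#' @export
size_class_table <- function(state, materials = material_set(), breaks = NULL) {
  if (inherits(state, "granulation_record")) state <- state$final_state
  props <- cell_properties(state, materials, floor_frac = 0)
  if (is.null(props)) {
    abort("content table undefined for an empty ensemble",
          class = "granupbm_undefined_statistics")
  }
  if (is.null(breaks)) {
    dd <- state$grid$diameters
    breaks <- c(0, sqrt(dd[-length(dd)] * dd[-1]), Inf)
  }
  cls <- cut(props$d, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  gmass <- props$n * props$mass
  api <- props$n * props$s1 * materials$rho_s1
  solid <- props$n * (props$s1 * materials$rho_s1 + props$s2 * materials$rho_s2)
  agg <- rowsum(cbind(gmass, api, solid), group = cls)
  ix <- as.integer(rownames(agg))
  tibble(
    d_lo = breaks[ix], d_hi = breaks[ix + 1],
    w = agg[, 1] / sum(agg[, 1]),
    x = ifelse(agg[, 3] > 0, agg[, 2] / agg[, 3], 0)
  )
}

#' Demixing potential
#'
#' A relative-standard-deviation-like measure of how unevenly the drug is
#' distributed across granule size classes:
#' `DP% = (100 / xbar) * sqrt(sum(w (x - xbar)^2))` with `xbar` the
#' weight-fraction-weighted mean content. Zero iff the content is the same in
#' every class; invariant to a common scaling of the contents.
#'
#' @param table A tibble with columns `w` (weight fractions summing to 1) and
#'   `x` (drug content per class), as from [size_class_table()].
#' @return DP in percent.
#' @export
demixing_potential <- function(table) {
  w <- table$w
  x <- table$x
  if (abs(sum(w) - 1) > 1e-6) {
    abort("class weight fractions must sum to 1", class = "granupbm_invalid_parameter")
  }
  xbar <- sum(w * x)
  if (xbar <= 0) {
    abort("demixing potential undefined: mean drug content is zero",
          class = "granupbm_undefined_statistics")
  }
  100 / xbar * sqrt(sum(w * (x - xbar)^2))
}

#' Ensemble-average granule properties
#'
#' Number- and volume-weighted averages of porosity, liquid fraction
#' `(le + li)/v` and drug content `q = s1/v`, plus the content offsets
#' `dq` (blend drug volume fraction minus the volume-weighted average `q`)
#' and `dq_solid` (blend drug solid-volume fraction minus the granules' drug
#' fraction of solids — the demixing-relevant, porosity-free basis).
#'
#' @param state A `granulation_state`.
#' @param materials A [material_set()].
#' @return A one-row tibble.
#' @export
ensemble_averages <- function(state, materials = material_set()) {
  if (inherits(state, "granulation_record")) state <- state$final_state
  props <- cell_properties(state, materials, floor_frac = 0)
  if (is.null(props)) {
    abort("averages undefined for an empty ensemble",
          class = "granupbm_undefined_statistics")
  }
  f1 <- materials$f1
  fv1 <- (f1 / materials$rho_s1) /
    (f1 / materials$rho_s1 + (1 - f1) / materials$rho_s2)
  eps <- props$p / props$v
  lf <- (props$le + props$li) / props$v
  q <- props$s1 / props$v
  wn <- props$n / sum(props$n)
  wv <- props$n * props$v / sum(props$n * props$v)
  s1_tot <- sum(props$n * props$s1)
  s_tot <- sum(props$n * (props$s1 + props$s2))
  tibble(
    avg_porosity_num = sum(wn * eps), avg_porosity_vol = sum(wv * eps),
    avg_liquid_frac_num = sum(wn * lf), avg_liquid_frac_vol = sum(wv * lf),
    avg_q_num = sum(wn * q), avg_q_vol = sum(wv * q),
    dq = fv1 - sum(wv * q),
    dq_solid = fv1 - if (s_tot > 0) s1_tot / s_tot else 0
  )
}

# One-row scalar summary used by the simulation recorder.
summarize_state <- function(state, config) {
  mats <- config$materials
  base <- tibble(time = state$time, n_granules = sum(state$F),
                 fss = state$Fss, ms1 = state$Ms1, ms2 = state$Ms2,
                 liquid_remaining = state$liquid_remaining,
                 squeeze_events = state$squeeze_events)
  if (sum(state$F) <= 0) {
    return(cbind(base, tibble(
      d10 = NA_real_, d50 = NA_real_, d90 = NA_real_,
      avg_porosity_num = NA_real_, avg_porosity_vol = NA_real_,
      avg_liquid_frac_num = NA_real_, avg_liquid_frac_vol = NA_real_,
      avg_q_num = NA_real_, avg_q_vol = NA_real_,
      dq = NA_real_, dq_solid = NA_real_, dp_percent = NA_real_
    )))
  }
  ss <- size_statistics(state, mats)
  av <- ensemble_averages(state, mats)
  # undefined for drug-free ensembles (e.g. single-component oracle runs)
  dp <- tryCatch(demixing_potential(size_class_table(state, mats)),
                 error = function(e) NA_real_)
  cbind(base, tibble(d10 = ss$d10, d50 = ss$d50, d90 = ss$d90), av,
        tibble(dp_percent = dp))
}

#' Perturbation sensitivity scan
#'
#' Re-runs the simulation with each tunable parameter perturbed by the given
#' fractions and reports `(Y0 - Yi) / Y0` for each output of interest, where
#' `Y0` is the unperturbed value. A zero perturbation gives identically zero
#' sensitivity; failed perturbed runs are marked missing and the scan
#' continues.
#'
#' @param config A [granulation_config()].
#' @param parameters Character vector of tunable parameter names (see
#'   [set_config_parameter()]); defaults to the six calibrated constants.
#' @param perturbations Fractional perturbations (default -20% to +20% in 10%
#'   steps, omitting 0).
#' @param outputs Which final-state outputs to track.
#' @return A `granulation_sensitivity` tibble: `parameter`, `perturbation`,
#'   one column per output, values `(Y0 - Yi)/Y0`.
#' @export
sensitivity_scan <- function(config,
                             parameters = c("beta0", "e_s1", "e_s2",
                                            "k_con", "k_layer", "k_sg"),
                             perturbations = c(-0.2, -0.1, 0.1, 0.2),
                             outputs = c("d10", "d50", "d90",
                                         "avg_porosity_vol", "avg_q_vol")) {
  base <- glance_outputs(run_simulation(config), outputs)
  rows <- list()
  for (par in parameters) {
    v0 <- get_config_parameter(config, par)
    for (pert in perturbations) {
      yi <- if (pert == 0) base else {
        cfg <- set_config_parameter(config, par, v0 * (1 + pert))
        tryCatch(glance_outputs(run_simulation(cfg), outputs),
                 error = function(e) setNames(rep(NA_real_, length(outputs)),
                                              outputs))
      }
      rows[[length(rows) + 1L]] <- tibble(
        parameter = par, perturbation = pert,
        !!!as.list((base - yi) / base)
      )
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("granulation_sensitivity", class(tibble())),
            base = base)
}

glance_outputs <- function(record, outputs) {
  last <- tail(record$series, 1)
  setNames(vapply(outputs, function(o) last[[o]], numeric(1)), outputs)
}
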