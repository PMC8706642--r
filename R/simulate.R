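#' CFL-bounded time step
#'
#' The explicit Euler step is bounded so that no size class loses more
#' particles than it holds: `dt = safety * min(F / outflow)` over cells with
#' positive outflow, capped by `dt_max`.
#'
#' @param n Particle counts (or reservoir contents) per cell.
#' @param outflow Corresponding outflow rates (per second, >= 0).
#' @param safety Safety factor in `(0, 1]`.
#' @param dt_max Upper bound on the step (s).
#' @return The admissible step (s).
#' @export
cfl_timestep <- function(n, outflow, safety, dt_max) {
  stopifnot(safety > 0, dt_max > 0)
  pos <- outflow > 0 & n > 0
  if (!any(pos)) return(dt_max)
  min(dt_max, safety * min(n[pos] / outflow[pos]))
}

#' Run a granulation simulation
#'
#' Integrates the three-coordinate population balance with first-order
#' explicit Euler and CFL-bounded adaptive steps. While binder remains the
#' run is in the liquid-addition phase (nucleation and rewetting active);
#' afterwards wet massing continues to `t_end` with aggregation, surface
#' growth, layering, consolidation and (optional) breakage only. All rates
#' are evaluated at the step-start state and applied in one synchronous
#' update; conservation of the drug, excipient and binder volume balances is
#' audited at every recorded time.
#'
#' @param config A [granulation_config()].
#' @param initial_state Optional pre-built `granulation_state` (e.g. for
#'   oracle runs with a hand-placed population); defaults to the pristine
#'   state of `config`.
#' @param keep_snapshots If `TRUE`, a long-format snapshot tibble is stored at
#'   every record time.
#' @return A `granulation_record`: list with `series` (tibble of scalar time
#'   series and audit errors), `final_state`, `config`, and optionally
#'   `snapshots`.
#' @export
run_simulation <- function(config, initial_state = NULL,
                           keep_snapshots = FALSE) {
  state <- if (is.null(initial_state)) new_granulation_state(config) else initial_state
  proc <- config$process
  mats <- config$materials
  num <- config$numerics
  t_end <- proc$t_end
  rows <- list()
  snaps <- list()
  next_rec <- 0
  step_count <- 0L

  record <- function(state, dt_used) {
    stats <- summarize_state(state, config)
    aud <- audit_state(state, config)
    cbind(stats, aud[, c("err_api", "err_excipient", "err_binder")],
          tibble(dt = dt_used))
  }

  repeat {
    if (state$time >= next_rec - 1e-12 || state$time >= t_end - 1e-12) {
      rows[[length(rows) + 1L]] <- record(state, NA_real_)
      if (keep_snapshots) snaps[[length(snaps) + 1L]] <- state_snapshot(state)
      while (next_rec <= state$time + 1e-12) next_rec <- next_rec + num$record_every
    }
    if (state$time >= t_end - 1e-12) break

    props <- cell_properties(state, mats)
    spray_active <- state$liquid_remaining > 1e-15 * state$binder_total

    # --- partition the spray between nucleation and rewetting -------------
    q_nuc <- 0
    q_rw <- 0
    if (spray_active) {
      f_bed <- if (identical(config$spray_split, "all_nucleation")) 1 else
        max(0, min(1, (state$Ms1 + state$Ms2) / proc$charge_mass))
      q_nuc <- f_bed * proc$q_spray
      q_rw <- proc$q_spray - q_nuc
    }
    rw <- rewetting_rates(props, q_rw)
    if (is.null(rw)) q_nuc <- q_nuc + q_rw  # no granules to rewet yet
    nuc <- if (q_nuc > 0) nucleation_rates(state, config, q_nuc) else NULL
    if (!is.null(nuc) && nuc$n_im + nuc$n_ss <= 0) nuc <- NULL

    lay <- layering_rates(props, state$Ms2, config$kinetics$k_layer, mats$rho_s2)
    sg <- surface_growth_rates(props, state, config)
    agg <- aggregation_rates(state, props, config)
    brk <- breakage_rates(props, state, config)

    # --- admissible step --------------------------------------------------
    dt <- min(num$dt_max, t_end - state$time)
    if (!is.null(props)) {
      outflow <- numeric(length(props$cell))
      if (!is.null(agg$dep_n)) outflow <- outflow + agg$dep_n
      if (!is.null(brk)) outflow <- outflow + brk$dep_n
      dt <- min(dt, cfl_timestep(props$n, outflow, num$safety, num$dt_max))
    }
    fss_out <- agg$fss_out + if (is.null(sg)) 0 else sg$consume
    if (fss_out > 0) {
      dt <- min(dt, cfl_timestep(state$Fss, fss_out, num$safety, num$dt_max))
    }
    if (!is.null(nuc)) {
      dt <- min(dt, cfl_timestep(c(state$Ms1, state$Ms2),
                                 c(nuc$dMs1, nuc$dMs2), num$safety, num$dt_max))
    }
    if (!is.null(lay)) {
      dt <- min(dt, cfl_timestep(state$Ms2, abs(lay$dMs2dt), num$safety, num$dt_max))
    }
    if (dt < num$dt_min && state$time + dt < t_end - 1e-12) {
      abort(sprintf("CFL-admissible step %.3g s fell below dt_min at t = %.3f s",
                    dt, state$time), class = "granupbm_cfl_failure")
    }

    state <- apply_step(state, config, dt, props, nuc, rw, lay, sg, agg, brk)
    step_count <- step_count + 1L
  }

  total_solid <- proc$charge_mass / ((mats$f1 * mats$rho_s1 +
                                        (1 - mats$f1) * mats$rho_s2))
  ovf <- abs(state$overflow[["s1"]]) + abs(state$overflow[["s2"]])
  if (ovf > 1e-3 * total_solid) {
    warn(sprintf("grid-boundary overflow reached %.2f%% of the solid volume",
                 100 * ovf / total_solid))
  }

  out <- list(series = dplyr::bind_rows(rows), final_state = state,
              config = config, n_steps = step_count)
  if (keep_snapshots) out$snapshots <- snaps
  structure(out, class = "granulation_record")
}

# One synchronous Euler update. All rates were evaluated at the step-start
# state; reservoir and binder draws are rescaled (never extrapolated) so no
# inventory goes negative.
apply_step <- function(state, config, dt, props, nuc, rw, lay, sg, agg, brk) {
  mats <- config$materials

  # -- exact binder bookkeeping for the spray-driven fluxes ----------------
  lam <- 1
  if (!is.null(nuc) || !is.null(rw)) {
    consume <- dt * ((if (is.null(nuc)) 0 else (nuc$n_im + nuc$n_ss) * state$nuclei$v_d) +
                       (if (is.null(rw)) 0 else sum(rw)))
    if (consume > state$liquid_remaining && consume > 0) {
      lam <- state$liquid_remaining / consume
    }
  }
  mu <- 1
  if (!is.null(nuc)) {
    need1 <- lam * dt * nuc$dMs1
    need2 <- lam * dt * nuc$dMs2
    mu <- min(1,
              if (need1 > 0) state$Ms1 / need1 else 1,
              if (need2 > 0) state$Ms2 / need2 else 1)
  }

  # -- depletion by aggregation and breakage -------------------------------
  if (!is.null(props)) {
    cells <- props$cell
    dep_n <- numeric(length(cells))
    if (!is.null(agg$dep_n)) dep_n <- dep_n + agg$dep_n
    if (!is.null(brk)) dep_n <- dep_n + brk$dep_n
    if (any(dep_n > 0)) {
      state$F[cells] <- pmax(0, state$F[cells] - dt * dep_n)
      state$Le[cells] <- pmax(0, state$Le[cells] - dt * dep_n * props$le)
      state$Li[cells] <- pmax(0, state$Li[cells] - dt * dep_n * props$li)
    }
  }

  # -- solid-spread class: marble-marble aggregation draw -------------------
  sg_scale <- 1
  if (!is.null(nuc)) state$Fss <- state$Fss + lam * mu * dt * nuc$n_ss
  fss_draw <- dt * agg$fss_out
  if (fss_draw > state$Fss && fss_draw > 0) {
    sg_scale <- state$Fss / fss_draw
  }
  state$Fss <- max(0, state$Fss - sg_scale * fss_draw)

  # -- gather all formation parcels and deposit once ------------------------
  ps1 <- ps2 <- pp <- pn <- ple <- pli <- numeric(0)
  add_parcel <- function(s1, s2, p, n, le, li) {
    ps1 <<- c(ps1, s1); ps2 <<- c(ps2, s2); pp <<- c(pp, p)
    pn <<- c(pn, n); ple <<- c(ple, le); pli <<- c(pli, li)
  }
  if (!is.null(agg$form)) {
    n <- dt * agg$form$rate
    add_parcel(agg$form$s1, agg$form$s2, agg$form$p, n,
               n * agg$form$le_pp, n * agg$form$li_pp)
  }
  if (!is.null(agg$form_ss)) {
    n <- sg_scale * dt * agg$form_ss$rate
    add_parcel(agg$form_ss$s1, agg$form_ss$s2, agg$form_ss$p, n,
               n * agg$form_ss$le_pp, n * agg$form_ss$li_pp)
  }
  if (!is.null(brk)) {
    n <- dt * brk$form$rate
    add_parcel(brk$form$s1, brk$form$s2, brk$form$p, n,
               n * brk$form$le_pp, n * brk$form$li_pp)
  }
  liquid_used <- 0
  if (!is.null(nuc)) {
    n_im <- lam * mu * dt * nuc$n_im
    if (n_im > 0) {
      add_parcel(nuc$s1_im, nuc$s2_im, state$nuclei$v_d, n_im,
                 0, n_im * state$nuclei$v_d)
    }
    n_ss <- lam * mu * dt * nuc$n_ss
    liquid_used <- liquid_used + (n_im + n_ss) * state$nuclei$v_d
    state$Ms1 <- max(0, state$Ms1 - lam * mu * dt * nuc$dMs1)
    state$Ms2 <- max(0, state$Ms2 - lam * mu * dt * nuc$dMs2)
  }
  if (length(pn) > 0) {
    state <- redistribute_cell_average(state, ps1, ps2, pp, pn, ple, pli)
  }

  # -- rewetting and marble-drop liquid delivery ---------------------------
  if (!is.null(rw)) {
    state$Le[props$cell] <- state$Le[props$cell] + lam * dt * rw
    liquid_used <- liquid_used + lam * dt * sum(rw)
  }
  state$liquid_remaining <- max(0, state$liquid_remaining - liquid_used)

  # -- coordinate movement: growth and consolidation, then re-binning ------
  # The per-particle increments are rated at the step-start state, but the
  # reservoir draws (marble class, excipient fines) are recomputed from the
  # population that actually moves, so the solid balances close exactly.
  if (!is.null(props)) {
    npc <- length(props$cell)
    n_cur_all <- state$F[props$cell]

    ds1 <- rep_len(0, npc)
    if (!is.null(sg)) {
      ds1 <- dt * sg$ds1dt
      delivered <- sum(n_cur_all * ds1) / state$nuclei$v_ss_s1  # marbles
      sgs <- if (delivered > state$Fss && delivered > 0) state$Fss / delivered else 1
      ds1 <- sgs * ds1
      consume_cells <- n_cur_all * ds1 / state$nuclei$v_ss_s1
      state$Fss <- max(0, state$Fss - sum(consume_cells))
      state$Le[props$cell] <- state$Le[props$cell] +
        consume_cells * state$nuclei$v_d
    }
    ds2 <- rep_len(0, npc)
    if (!is.null(lay)) {
      ds2 <- dt * lay$ds2dt
      need <- mats$rho_s2 * sum(n_cur_all * ds2)
      lay_scale <- if (need > state$Ms2 && need > 0) state$Ms2 / need else 1
      ds2 <- lay_scale * ds2
      state$Ms2 <- max(0, state$Ms2 - lay_scale * need)
    }
    con <- consolidation_update(props, config, dt)
    p_new <- if (is.null(con)) props$p else con$p_new
    squeeze <- if (is.null(con)) rep_len(0, npc) else con$squeeze
    moved <- which(abs(ds1) + abs(ds2) + abs(p_new - props$p) > 0)
    if (length(moved) > 0) {
      if (!is.null(con)) state$squeeze_events <- state$squeeze_events + con$n_squeeze
      cells <- props$cell[moved]
      n_cur <- state$F[cells]
      le_cur <- state$Le[cells]
      li_cur <- state$Li[cells]
      sq <- squeeze[moved] * n_cur
      le_cur <- le_cur + sq
      li_cur <- pmax(0, li_cur - sq)
      state$F[cells] <- 0
      state$Le[cells] <- 0
      state$Li[cells] <- 0
      state <- redistribute_cell_average(
        state,
        props$s1[moved] + ds1[moved],
        props$s2[moved] + ds2[moved],
        p_new[moved],
        n_cur, le_cur, li_cur
      )
    }
  }

  state$time <- state$time + dt
  state
}

#' @export
print.granulation_record <- function(x, ...) {
  last <- tail(x$series, 1)
  cat(sprintf(
    "<granulation_record> %d steps to t = %.1f s | d50 = %.0f um | DP = %.2f%% | max audit err %.1e\n",
    x$n_steps, last$time, last$d50 * 1e6, last$dp_percent,
    max(last$err_api, last$err_excipient, last$err_binder)
  ))
  invisible(x)
}

#' @rdname tidy_granupbm
#' @method tidy granulation_record
#' @export
tidy.granulation_record <- function(x, ...) x$series

#' Tidiers for granulation results
#'
#' `tidy()` on a `granulation_record` returns the scalar time-series tibble
#' (one row per recorded time); `glance()` returns a one-row summary of the
#' final state.
#'
#' @param x A `granulation_record`.
#' @param ... Unused.
#' @name tidy_granupbm
#' @method glance granulation_record
#' @export
glance.granulation_record <- function(x, ...) {
  last <- tail(x$series, 1)
  dplyr::select(last, "time", "n_granules", "fss", "d10", "d50", "d90",
                "avg_porosity_vol", "avg_liquid_frac_vol", "avg_q_vol",
                "dq", "dq_solid", "dp_percent",
                "err_api", "err_excipient", "err_binder")
}
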