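#' Generate a synthetic "experiment" fixture
#'
#' Runs the forward model under a known parameter vector and converts the
#' final state into the two measurement tables a granulation experiment
#' yields: a cumulative size distribution sampled at the grid's bin
#' diameters, and a per-size-class drug content table. Multiplicative
#' Gaussian noise of relative standard deviation `noise_sd` is applied to the
#' observations (the cumulative curve is re-monotonized and clipped to
#' `[0, 1]`). Fully reproducible from `seed`.
#'
#' @param config A [granulation_config()] describing the emulated experiment.
#' @param true_params Named list/vector overriding any of the six tunable
#'   constants (`beta0`, `e_s1`, `e_s2`, `k_con`, `k_layer`, `k_sg`).
#' @param noise_sd Relative noise level (0 = noiseless).
#' @param seed Integer seed.
#' @return A `granulation_fixture`: list with `csd` (tibble `diameter`,
#'   `cum_vol_frac`), `content` (tibble `d_lo`, `d_hi`, `w`, `x`) and `meta`.
#' @export
make_fixture <- function(config, true_params = list(), noise_sd = 0,
                         seed = 1) {
  cfg <- apply_params(config, true_params)
  rec <- run_simulation(cfg)
  mats <- cfg$materials
  grid_d <- rec$final_state$grid$diameters
  ss <- size_statistics(rec$final_state, mats)
  csd <- tibble(
    diameter = grid_d,
    cum_vol_frac = approx(ss$curve$diameter, ss$curve$cum_vol_frac,
                          xout = grid_d, rule = 2, ties = "ordered")$y
  )
  content <- size_class_table(rec$final_state, mats)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    csd$cum_vol_frac <- csd$cum_vol_frac *
      (1 + rnorm(nrow(csd), sd = noise_sd))
    csd$cum_vol_frac <- pmin(1, pmax(0, cummax(csd$cum_vol_frac)))
    content$x <- pmin(1, pmax(0, content$x * (1 + rnorm(nrow(content), sd = noise_sd))))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(
    list(csd = csd, content = content,
         meta = list(config = cfg, true_params = true_params,
                     noise_sd = noise_sd, seed = seed,
                     f1 = mats$f1, ls_ratio = cfg$process$ls_ratio)),
    class = "granulation_fixture"
  )
}

apply_params <- function(config, params) {
  for (nm in names(params)) {
    config <- set_config_parameter(config, nm, params[[nm]])
  }
  config
}

#' Calibration objectives for one candidate parameter vector
#'
#' Runs the forward model under the candidate parameters on the fixture's
#' configuration and returns the sum of squared errors between simulated and
#' fixture cumulative size fractions (at the fixture's diameters) and between
#' simulated and fixture per-class drug contents (weighted by the fixture's
#' class weight fractions, so empty classes do not dominate). A failed
#' simulation yields `Inf` sentinels.
#'
#' @param candidate_params Named list/vector of tunable constants.
#' @param fixture A `granulation_fixture`.
#' @return Named numeric vector `c(sse_size, sse_content)`.
#' @export
calibration_objectives <- function(candidate_params, fixture) {
  cfg <- apply_params(fixture$meta$config, candidate_params)
  rec <- tryCatch(run_simulation(cfg), error = function(e) NULL)
  if (is.null(rec) || sum(rec$final_state$F) <= 0) {
    return(c(sse_size = Inf, sse_content = Inf))
  }
  mats <- cfg$materials
  ss <- size_statistics(rec$final_state, mats)
  sim_cum <- approx(ss$curve$diameter, ss$curve$cum_vol_frac,
                    xout = fixture$csd$diameter, rule = 2, ties = "ordered")$y
  sse_size <- sum((sim_cum - fixture$csd$cum_vol_frac)^2)
  sim_tab <- size_class_table(rec$final_state, mats,
                              breaks = c(fixture$content$d_lo[1],
                                         fixture$content$d_hi))
  # align classes by lower edge
  x_sim <- sim_tab$x[match(round(log(fixture$content$d_lo + 1e-30), 6),
                           round(log(sim_tab$d_lo + 1e-30), 6))]
  x_sim[is.na(x_sim)] <- 0
  sse_content <- sum(fixture$content$w * (x_sim - fixture$content$x)^2)
  c(sse_size = sse_size, sse_content = sse_content)
}

#' Two-objective Pareto parameter estimation
#'
#' Estimates the six tunable constants by weighted-sum scalarization of the
#' size and content objectives: for each weight `w` in a grid over `[0, 1]`
#' a bounded derivative-free Nelder--Mead search minimizes
#' `w * SSE_size / S0 + (1 - w) * SSE_content / C0` (objectives normalized by
#' their start values), the rate constants searched in log space and the
#' restitution coefficients in logit space, bounds enforced by penalty.
#' Dominated solutions are pruned and a compromise member is selected as the
#' knee point (minimum normalized distance to the ideal point).
#'
#' @param fixtures A `granulation_fixture` or list of them; objectives are
#'   summed over fixtures.
#' @param bounds Named list of `c(lo, hi)` per parameter; defaults to a
#'   decade either side of the nominal constants and `[0.01, 0.9]` for the
#'   restitution coefficients.
#' @param n_weights Number of scalarization weights.
#' @param start Named list of starting values; defaults to the nominal
#'   constants.
#' @param seed Integer seed (the search is deterministic; the seed is fixed
#'   for reproducibility of any stochastic extension).
#' @param maxit Maximum Nelder--Mead iterations per weight.
#' @return A `granulation_calibration`: list with `members` (tibble of
#'   parameter vectors and objectives, mutually non-dominated), `compromise`
#'   (one-row tibble) and `trace`.
#' @export
pareto_fit <- function(fixtures, bounds = NULL, n_weights = 3, start = NULL,
                       seed = 1, maxit = 200, restarts = 1) {
  if (inherits(fixtures, "granulation_fixture")) fixtures <- list(fixtures)
  stopifnot(length(fixtures) >= 1)
  nominal <- list(beta0 = 4.34e-10, e_s1 = 0.162, e_s2 = 0.07,
                  k_con = 1.67e-3, k_layer = 2.01e-8, k_sg = 4.59e-11)
  log_pars <- c("beta0", "k_con", "k_layer", "k_sg")
  if (is.null(bounds)) {
    bounds <- lapply(nominal, function(v) c(v / 10, v * 10))
    bounds$e_s1 <- c(0.01, 0.9)
    bounds$e_s2 <- c(0.01, 0.9)
  }
  if (is.null(start)) start <- nominal
  pars <- names(nominal)

  to_t <- function(x) {
    vapply(pars, function(p) {
      if (p %in% log_pars) log(x[[p]])
      else stats::qlogis((x[[p]] - bounds[[p]][1]) /
                           diff(bounds[[p]]))
    }, numeric(1))
  }
  from_t <- function(tv) {
    out <- lapply(seq_along(pars), function(i) {
      p <- pars[i]
      if (p %in% log_pars) exp(tv[i])
      else bounds[[p]][1] + diff(bounds[[p]]) * stats::plogis(tv[i])
    })
    names(out) <- pars
    out
  }
  penalty <- function(x) {
    sum(vapply(pars, function(p) {
      lo <- bounds[[p]][1]; hi <- bounds[[p]][2]
      v <- x[[p]]
      if (v < lo || v > hi) 1e6 * (1 + abs(log(pmax(v, 1e-300) / ifelse(v < lo, lo, hi)))) else 0
    }, numeric(1)))
  }
  eval_objs <- function(x) {
    o <- vapply(fixtures, function(fx) calibration_objectives(x, fx),
                numeric(2))
    rowSums(matrix(o, nrow = 2))
  }

  set.seed(seed)
  o_start <- eval_objs(start)
  norm <- pmax(o_start, 1e-12)
  weights <- if (n_weights == 1) 0.5 else seq(0, 1, length.out = n_weights)
  trace <- list()
  members <- list()
  for (w in weights) {
    fn <- function(tv) {
      x <- from_t(tv)
      o <- eval_objs(x)
      if (!all(is.finite(o))) return(1e12)
      w * o[1] / norm[1] + (1 - w) * o[2] / norm[2] + penalty(x)
    }
    fit <- optim(to_t(start), fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    for (r in seq_len(restarts)) {
      # re-initialize the simplex at the incumbent; cheap escape from the
      # collapsed-simplex stalls Nelder-Mead is prone to in 6 dimensions
      fit2 <- optim(fit$par, fn, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
      if (fit2$value < fit$value) fit <- fit2
    }
    x <- from_t(fit$par)
    o <- eval_objs(x)
    members[[length(members) + 1L]] <- tibble(
      weight = w, !!!x, sse_size = o[1], sse_content = o[2],
      converged = fit$convergence == 0
    )
    trace[[length(trace) + 1L]] <- fit
  }
  tab <- dplyr::bind_rows(members)
  keep <- !vapply(seq_len(nrow(tab)), function(i) {
    any(tab$sse_size < tab$sse_size[i] - 1e-15 &
          tab$sse_content <= tab$sse_content[i] |
          tab$sse_size <= tab$sse_size[i] &
          tab$sse_content < tab$sse_content[i] - 1e-15)
  }, logical(1))
  tab <- tab[keep, , drop = FALSE]
  ideal <- c(min(tab$sse_size), min(tab$sse_content))
  span <- pmax(c(diff(range(tab$sse_size)), diff(range(tab$sse_content))),
               1e-15)
  dist <- sqrt(((tab$sse_size - ideal[1]) / span[1])^2 +
                 ((tab$sse_content - ideal[2]) / span[2])^2)
  structure(
    list(members = tab, compromise = tab[which.min(dist), , drop = FALSE],
         trace = trace, bounds = bounds, start = start),
    class = "granulation_calibration"
  )
}

#' @export
print.granulation_calibration <- function(x, ...) {
  cat(sprintf("<granulation_calibration> %d Pareto member(s)\n", nrow(x$members)))
  print(x$compromise)
  invisible(x)
}

#' @rdname tidy_granupbm
#' @method tidy granulation_calibration
#' @export
tidy.granulation_calibration <- function(x, ...) x$members

#' @rdname tidy_granupbm
#' @method glance granulation_calibration
#' @export
glance.granulation_calibration <- function(x, ...) x$compromise

#' Write / read fixture tables as plain CSV
#'
#' @param fixture A `granulation_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_csv <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(fixture$csd, file.path(dir, "csd.csv"), row.names = FALSE)
  write.csv(fixture$content, file.path(dir, "content.csv"), row.names = FALSE)
  meta <- fixture$meta
  write.csv(tibble(f1 = meta$f1, ls_ratio = meta$ls_ratio,
                   noise_sd = meta$noise_sd, seed = meta$seed),
            file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}
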