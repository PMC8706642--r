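#' Create an empty granulation state
#'
#' The state holds the discretized number density `F` over the three internal
#' coordinates (drug volume, excipient volume, pore volume), the per-cell
#' external and internal liquid *totals* `Le` and `Li` (totals rather than the
#' per-particle averages so that conservation bookkeeping is exact; averages
#' are recovered by dividing by `F`), the scalar solid-spread nucleus class
#' `Fss` with its fixed geometry, the un-granulated powder reservoirs, the
#' binder accounting, and signed overflow ledgers for volume clamped at the
#' grid boundaries.
#'
#' Arrays are dimensioned `(n_bins + 1)^3`: index 1 on each coordinate is a
#' zero node so granules may carry exactly zero of a coordinate.
#'
#' @param config A [granulation_config()].
#' @return A `granulation_state` list.
#' @export
new_granulation_state <- function(config) {
  mats <- config$materials
  proc <- config$process
  num <- config$numerics
  grid <- build_grid(num$base_diameter, num$max_diameter, num$n_bins,
                     num$ratio_mode)
  nn <- grid$n_bins + 1L
  zero <- array(0, dim = c(nn, nn, nn))
  d_ss <- proc$d_d + 2 * mats$d_p
  v_ss <- sphere_volume(d_ss)
  structure(
    list(
      grid = grid,
      F = zero, Le = zero, Li = zero,
      Fss = 0,
      nuclei = list(v_d = proc$v_d, d_ss = d_ss, v_ss = v_ss,
                    v_ss_s1 = v_ss - proc$v_d),
      Ms1 = mats$f1 * proc$charge_mass,
      Ms2 = (1 - mats$f1) * proc$charge_mass,
      binder_total = proc$ls_ratio * proc$charge_mass / mats$rho_l,
      liquid_remaining = proc$ls_ratio * proc$charge_mass / mats$rho_l,
      overflow = c(s1 = 0, s2 = 0, p = 0, liquid = 0),
      squeeze_events = 0L,
      time = 0
    ),
    class = "granulation_state"
  )
}

#' @export
print.granulation_state <- function(x, ...) {
  cat(sprintf(
    "<granulation_state> t = %.2f s | granules %.4g | marbles %.4g | Ms1 %.4g kg | Ms2 %.4g kg\n",
    x$time, sum(x$F), x$Fss, x$Ms1, x$Ms2
  ))
  invisible(x)
}

#' Deposit particle parcels onto the grid by the cell-average rule
#'
#' Each parcel (a target point in `(s1, s2, p)` space, a particle count and
#' attached external/internal liquid totals) is split onto the 8 surrounding
#' grid nodes coordinate-by-coordinate: per coordinate the two bracketing
#' nodes receive fractions solving the two-moment linear system (number and
#' first moment both conserved). Attached liquid is apportioned in the same
#' fractions as number. Targets outside the grid are clamped to the boundary
#' node and the volume discrepancy is added to the signed overflow ledger, so
#' global balances close exactly.
#'
#' @param state A `granulation_state`.
#' @param s1,s2,p Target coordinates (m^3), vectors of equal length.
#' @param n Particle counts per parcel (>= 0).
#' @param le,li Attached external / internal liquid totals per parcel (m^3).
#' @return The updated state.
#' @export
redistribute_cell_average <- function(state, s1, s2, p, n, le = 0, li = 0) {
  if (any(n < 0)) {
    abort("parcel counts must be non-negative", class = "granupbm_invalid_rate")
  }
  keep <- n > 0
  if (!any(keep)) return(state)
  nt <- sum(keep)
  s1 <- s1[keep]; s2 <- s2[keep]; p <- p[keep]; n <- n[keep]
  le <- rep_len(le, length(keep))[keep]
  li <- rep_len(li, length(keep))[keep]

  u <- state$grid$nodes
  nn <- length(u)
  br <- function(x) {
    i <- findInterval(x, u, all.inside = TRUE)
    w <- (u[i + 1L] - x) / (u[i + 1L] - u[i])
    w <- pmin(1, pmax(0, w))
    list(i = i, w = w)
  }
  b1 <- br(s1); b2 <- br(s2); b3 <- br(p)

  idx <- integer(8L * nt)
  wn <- numeric(8L * nt)
  k <- 0L
  for (c1 in 0:1) {
    w1 <- if (c1 == 0) b1$w else 1 - b1$w
    i1 <- b1$i + c1
    for (c2 in 0:1) {
      w12 <- w1 * (if (c2 == 0) b2$w else 1 - b2$w)
      i12 <- i1 + (b2$i + c2 - 1L) * nn
      for (c3 in 0:1) {
        w <- w12 * (if (c3 == 0) b3$w else 1 - b3$w)
        sl <- k * nt + seq_len(nt)
        idx[sl] <- i12 + (b3$i + c3 - 1L) * nn * nn
        wn[sl] <- w
        k <- k + 1L
      }
    }
  }
  nt8 <- rep.int(n, 8L)
  acc <- rowsum(cbind(nt8 * wn, rep.int(le, 8L) * wn, rep.int(li, 8L) * wn),
                group = idx, reorder = FALSE)
  cells <- as.integer(rownames(acc))
  state$F[cells] <- state$F[cells] + acc[, 1]
  state$Le[cells] <- state$Le[cells] + acc[, 2]
  state$Li[cells] <- state$Li[cells] + acc[, 3]

  # signed boundary-overflow ledger: target moment minus deposited moment
  dep1 <- b1$w * u[b1$i] + (1 - b1$w) * u[b1$i + 1L]
  dep2 <- b2$w * u[b2$i] + (1 - b2$w) * u[b2$i + 1L]
  dep3 <- b3$w * u[b3$i] + (1 - b3$w) * u[b3$i + 1L]
  state$overflow["s1"] <- state$overflow["s1"] + sum(n * (s1 - dep1))
  state$overflow["s2"] <- state$overflow["s2"] + sum(n * (s2 - dep2))
  state$overflow["p"] <- state$overflow["p"] + sum(n * (p - dep3))
  state
}

#' Derived per-cell granule properties of the occupied cells
#'
#' @param state A `granulation_state`.
#' @param materials A [material_set()].
#' @param floor_frac Cells holding fewer than `floor_frac` times the total
#'   particle number are left in place but excluded from rate evaluation.
#' @return A list of parallel vectors over occupied cells: linear `cell`
#'   index, coordinates, per-particle liquid, volume, area, diameter, mass
#'   and granule restitution coefficient.
#' @keywords internal
cell_properties <- function(state, materials, floor_frac = 1e-12) {
  ntot <- sum(state$F)
  floor_n <- ntot * floor_frac
  occ <- which(state$F > floor_n)
  if (length(occ) == 0) return(NULL)
  u <- state$grid$nodes
  nn <- length(u)
  i3 <- arrayInd(occ, .dim = c(nn, nn, nn))
  Fo <- state$F[occ]
  s1 <- u[i3[, 1]]
  s2 <- u[i3[, 2]]
  p <- u[i3[, 3]]
  le <- state$Le[occ] / Fo
  li <- state$Li[occ] / Fo
  v <- s1 + s2 + le + p
  solid_mass <- materials$rho_s1 * s1 + materials$rho_s2 * s2
  e <- ifelse(solid_mass > 0,
              (materials$e_s1 * materials$rho_s1 * s1 +
                 materials$e_s2 * materials$rho_s2 * s2) / solid_mass,
              0)
  list(cell = occ, n = Fo, s1 = s1, s2 = s2, p = p, le = le, li = li,
       v = v, a = surface_area(v), d = sphere_diameter(v),
       mass = solid_mass + materials$rho_l * (le + li), e = e)
}

#' Conservation audit of a state
#'
#' Relative closure errors of the drug-volume, excipient-volume and
#' binder-volume balances across the grid, the marble class, the reservoirs
#' and the boundary-overflow ledger.
#'
#' @param state A `granulation_state`.
#' @param config The matching configuration.
#' @return A tibble with one row: `err_api`, `err_excipient`, `err_binder`
#'   (relative to the initial inventories).
#' @export
audit_state <- function(state, config) {
  mats <- config$materials
  proc <- config$process
  u <- state$grid$nodes
  nn <- length(u)
  m1 <- rep(u, times = nn * nn)           # s1 coordinate varies fastest
  m2 <- rep(rep(u, each = nn), times = nn)
  m3 <- rep(u, each = nn * nn)
  api0 <- mats$f1 * proc$charge_mass / mats$rho_s1
  exc0 <- (1 - mats$f1) * proc$charge_mass / mats$rho_s2
  b0 <- state$binder_total
  api <- sum(state$F * m1) + state$Ms1 / mats$rho_s1 +
    state$Fss * state$nuclei$v_ss_s1 + state$overflow[["s1"]]
  exc <- sum(state$F * m2) + state$Ms2 / mats$rho_s2 + state$overflow[["s2"]]
  binder <- sum(state$Le) + sum(state$Li) + state$Fss * state$nuclei$v_d +
    state$liquid_remaining + state$overflow[["liquid"]]
  tibble(
    time = state$time,
    err_api = abs(api - api0) / api0,
    err_excipient = abs(exc - exc0) / exc0,
    err_binder = abs(binder - b0) / b0
  )
}

#' Long-format snapshot of the occupied cells
#'
#' @param state A `granulation_state`.
#' @return A tibble with columns `i, j, k` (bin indices, 0 = zero node),
#'   `s1, s2, p` (node volumes, m^3), `F`, `Le`, `Li`.
#' @export
state_snapshot <- function(state) {
  occ <- which(state$F > 0)
  u <- state$grid$nodes
  nn <- length(u)
  i3 <- arrayInd(occ, .dim = c(nn, nn, nn))
  tibble(
    i = i3[, 1] - 1L, j = i3[, 2] - 1L, k = i3[, 3] - 1L,
    s1 = u[i3[, 1]], s2 = u[i3[, 2]], p = u[i3[, 3]],
    F = state$F[occ], Le = state$Le[occ], Li = state$Li[occ]
  )
}
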