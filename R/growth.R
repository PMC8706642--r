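#' Rewetting deposition rates
#'
#' Spray liquid that lands on already-formed granules is deposited on their
#' surfaces in proportion to each cell's share of the total granule volume,
#' `F v / sum(F v)`; the per-cell rates sum exactly to the rewetting flux.
#'
#' @param props Occupied-cell properties from `cell_properties()`.
#' @param q_rewet Rewetting volumetric flux (m^3/s).
#' @return Per-occupied-cell `dLe/dt` totals (m^3/s), or `NULL` when the
#'   ensemble is empty (the caller returns the liquid to the nucleation flux).
#' @keywords internal
rewetting_rates <- function(props, q_rewet) {
  if (is.null(props) || q_rewet <= 0) return(NULL)
  fv <- props$n * props$v
  tot <- sum(fv)
  if (tot <= 0) return(NULL)
  q_rewet * fv / tot
}

#' Excipient layering rates
#'
#' Fine excipient powder adheres to wet granule surfaces: per particle
#' `ds2/dt = k_layer * a * Ms2 / rho_s2` on cells whose surface carries
#' external liquid, zero on dry cells. The reservoir depletion rate is the
#' mass-consistent total `dMs2/dt = -rho_s2 * sum(F ds2/dt)`.
#'
#' @param props Occupied-cell properties.
#' @param Ms2 Excipient powder reservoir (kg).
#' @param k_layer Layering rate constant (1/(m^2 s)).
#' @param rho_s2 Excipient true density (kg/m^3).
#' @return List with per-particle `ds2dt` (m^3/s) and scalar `dMs2dt` (kg/s).
#' @keywords internal
layering_rates <- function(props, Ms2, k_layer, rho_s2) {
  if (is.null(props) || Ms2 <= 0 || k_layer <= 0) return(NULL)
  wet <- props$le > 0
  ds2dt <- ifelse(wet, k_layer * props$a * Ms2 / rho_s2, 0)
  list(ds2dt = ds2dt, dMs2dt = -rho_s2 * sum(props$n * ds2dt))
}

#' Solid-spread surface-growth rates
#'
#' Liquid marbles rupture and spread onto granules large enough that the
#' impact flattens the marble past its rupture extension: the marble's
#' maximum spread diameter is `D_max = D_ss (1 + 0.12 We)` with the Weber
#' number `We = rho_l v_r^2 D_ss / sigma`, and only granules with
#' sphere-equivalent diameter `>= D_max` grow. Eligible granules gain drug
#' volume at `ds1/dt = k_sg v^(2/3) Fss` (proportional to marble
#' availability, so the flux is self-limited by the marble reservoir); each
#' consumed marble also delivers its drop volume to the receiving cell's
#' external liquid.
#'
#' @param props Occupied-cell properties.
#' @param state The `granulation_state` (for `Fss` and nucleus geometry).
#' @param config The configuration.
#' @return List with per-particle `ds1dt`, per-cell external-liquid rate
#'   `dledt_tot` (totals, m^3/s) and scalar marble consumption rate
#'   `consume` (1/s), or `NULL` when inactive.
#' @keywords internal
surface_growth_rates <- function(props, state, config) {
  k_sg <- config$kinetics$k_sg
  if (is.null(props) || state$Fss <= 0 || k_sg <= 0) return(NULL)
  mats <- config$materials
  proc <- config$process
  d_ss <- state$nuclei$d_ss
  v_r <- granular_velocity(proc$gamma, d_ss, proc$phi_p)
  we <- mats$rho_l * v_r^2 * d_ss / mats$sigma
  d_max <- d_ss * (1 + 0.12 * we)
  elig <- props$d >= d_max
  if (!any(elig)) return(NULL)
  ds1dt <- ifelse(elig, k_sg * props$v^(2 / 3) * state$Fss, 0)
  consume_cell <- props$n * ds1dt / state$nuclei$v_ss_s1  # marbles/s per cell
  list(ds1dt = ds1dt,
       dledt_tot = consume_cell * state$nuclei$v_d,
       consume = sum(consume_cell))
}

#' Consolidation update of one step
#'
#' Collisions compact granules: the porosity decrement is
#' `d(eps) = k_con U (eps - eps_min) dt` while it keeps `eps >= eps_min`,
#' with the collision velocity `U` taken from the granular-temperature
#' relative velocity at each cell's diameter. The pore volume is closed from
#' the new porosity; if the shrunken pores can no longer hold the internal
#' liquid (squeeze), the excess is expelled to the surface (`li = p`).
#'
#' @param props Occupied-cell properties.
#' @param config The configuration.
#' @param dt Time step (s).
#' @return List with per-particle new pore volume `p_new`, per-particle
#'   liquid transfer `squeeze` (m^3, `li -> le`), and a squeeze event count.
#' @keywords internal
consolidation_update <- function(props, config, dt) {
  k_con <- config$kinetics$k_con
  if (is.null(props) || k_con <= 0) return(NULL)
  mats <- config$materials
  proc <- config$process
  eps <- props$p / props$v
  u_col <- granular_velocity(proc$gamma, props$d, proc$phi_p)
  d_eps <- k_con * u_col * pmax(0, eps - mats$eps_min) * dt
  eps_new <- pmax(mats$eps_min, eps - d_eps)
  active <- eps_new < eps
  if (!any(active)) return(NULL)
  solids_le <- props$s1 + props$s2 + props$le
  # non-squeeze closure: p'/(solids + le + p') = eps'
  p_new <- eps_new / (1 - eps_new) * solids_le
  squeeze <- pmax(0, props$li - p_new)
  sq <- squeeze > 0
  if (any(sq)) {
    # pores saturated: li' = p', le' = le + (li - p'), v' = s1+s2+le+li
    v_sat <- props$s1[sq] + props$s2[sq] + props$le[sq] + props$li[sq]
    p_sat <- eps_new[sq] * v_sat
    p_new[sq] <- p_sat
    squeeze[sq] <- pmax(0, props$li[sq] - p_sat)
  }
  # do not let consolidation *increase* pore volume (degenerate closures)
  p_new <- pmin(p_new, props$p)
  squeeze <- pmax(0, pmin(squeeze, props$li))
  list(p_new = ifelse(active, p_new, props$p),
       squeeze = ifelse(active, squeeze, 0),
       n_squeeze = sum(sq))
}
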