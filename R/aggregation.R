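#' Construct a granule property tuple
#'
#' Convenience constructor for the single-granule tuples accepted by the
#' pairwise collision operations.
#'
#' @param s1,s2 Drug / excipient solid volumes (m^3).
#' @param p Pore volume (m^3).
#' @param le,li External / internal liquid volumes (m^3).
#' @return A named list.
#' @export
granule_tuple <- function(s1, s2, p = 0, le = 0, li = 0) {
  list(s1 = s1, s2 = s2, p = p, le = le, li = li)
}

tuple_derived <- function(g, materials) {
  v <- g$s1 + g$s2 + g$le + g$p
  sm <- materials$rho_s1 * g$s1 + materials$rho_s2 * g$s2
  e <- ifelse(sm > 0,
              (materials$e_s1 * materials$rho_s1 * g$s1 +
                 materials$e_s2 * materials$rho_s2 * g$s2) / sm,
              0)
  list(v = v, a = surface_area(v), d = sphere_diameter(v),
       mass = sm + materials$rho_l * (g$le + g$li), e = e)
}

#' Pair restitution and deformability
#'
#' Each granule's coefficient of restitution is the mass-weighted mean of its
#' constituents' coefficients over (drug, excipient, pore), with the pore
#' contributing restitution 0 at zero mass. The pair coefficient is
#' `e_coag = e_A e_B` and the deformability is `zeta = 1 - e_coag`.
#'
#' @param A,B Granule tuples (see [granule_tuple()]).
#' @param materials A [material_set()] supplying densities and the component
#'   restitution coefficients.
#' @return List with `e_A`, `e_B`, `e_coag`, `zeta`.
#' @export
restitution_pair <- function(A, B, materials) {
  mA <- materials$rho_s1 * A$s1 + materials$rho_s2 * A$s2
  mB <- materials$rho_s1 * B$s1 + materials$rho_s2 * B$s2
  if (any(mA <= 0) || any(mB <= 0)) {
    abort("granules must carry solid mass", class = "granupbm_invalid_pair")
  }
  eA <- tuple_derived(A, materials)$e
  eB <- tuple_derived(B, materials)$e
  ec <- eA * eB
  list(e_A = eA, e_B = eB, e_coag = ec, zeta = 1 - ec)
}

#' Mean relative collision velocity from the granular temperature
#'
#' `Theta = (5 pi / 96) gamma^2 d^2 g(phi_p)` with the volume-fraction
#' closure `g(phi_p) = 1 / (12 phi_p^2 (1 - phi_p))`, and
#' `v_r = sqrt(32 Theta / pi)`, so `v_r` scales linearly in both the shear
#' rate and the granule diameter.
#'
#' @param gamma Shear rate (1/s).
#' @param d Granule diameter (m), vectorised.
#' @param phi_p Particle volume fraction in the granulator, `(0, 1)`.
#' @param g_phi Optional replacement volume-fraction closure, a function of
#'   `phi_p`.
#' @return Relative velocity (m/s).
#' @export
granular_velocity <- function(gamma, d, phi_p, g_phi = NULL) {
  if (phi_p <= 0 || phi_p >= 1) {
    abort("phi_p must lie strictly in (0, 1)", class = "granupbm_invalid_parameter")
  }
  stopifnot(gamma > 0, all(d > 0))
  g <- if (is.null(g_phi)) 1 / (12 * phi_p^2 * (1 - phi_p)) else g_phi(phi_p)
  theta <- (5 * pi / 96) * gamma^2 * d^2 * g
  sqrt(32 * theta / pi)
}

#' Work of the dissipative (viscous) bridge force
#'
#' `W_d = (3 pi mu dtilde^2 e_coag v_r / 4) ln(h / h_a)` for a binder layer
#' thicker than the surface asperities, and 0 otherwise (no bridge forms).
#'
#' @param d_tilde Harmonic-mean diameter of the colliding pair (m).
#' @param mu Binder viscosity (Pa s).
#' @param e_coag Pair restitution coefficient.
#' @param v_r Relative collision velocity (m/s).
#' @param h Binder layer thickness (m).
#' @param h_a Surface asperity height (m).
#' @return Dissipative work (J), vectorised.
#' @export
dissipative_work <- function(d_tilde, mu, e_coag, v_r, h, h_a) {
  ifelse(h > h_a,
         3 * pi * mu * d_tilde^2 * e_coag * v_r / 4 * log(h / h_a),
         0)
}

#' Work of the capillary bridge force
#'
#' The capillary work is the composition-dependent capillary number (ratio of
#' capillary to viscous bridge force) times the pair's viscous reference
#' work: `W_c = Ca(f_api) * W_ref`.
#'
#' @param f_api Drug solid volume fraction of the pair, `[0, 1]`.
#' @param ca_model A capillary-number function, e.g.
#'   [capillary_number_model()].
#' @param reference_visc_work Viscous reference work (J).
#' @return Capillary work (J), vectorised.
#' @export
capillary_work <- function(f_api, ca_model, reference_visc_work) {
  if (any(f_api < 0 | f_api > 1)) {
    abort("f_api must lie in [0, 1]", class = "granupbm_invalid_parameter")
  }
  pmax(0, ca_model(f_api)) * reference_visc_work
}

# Vectorised collision efficiency over parallel pair vectors. Each input is a
# list with fields s1, s2, p, le, li, v, a, d, mass, e.
collision_efficiency_vec <- function(A, B, config) {
  if (identical(config$kernel_override, "constant")) {
    return(rep_len(1, length(A$v)))
  }
  mats <- config$materials
  proc <- config$process
  d_tilde <- 2 * A$d * B$d / (A$d + B$d)
  v_r <- granular_velocity(proc$gamma, d_tilde, proc$phi_p)
  e_coag <- A$e * B$e
  h <- (A$le / A$a + B$le / B$a) / 2
  wd <- dissipative_work(d_tilde, mats$mu, e_coag, v_r, h, mats$h_a)
  solids <- A$s1 + A$s2 + B$s1 + B$s2
  f_api <- ifelse(solids > 0, (A$s1 + B$s1) / solids, 0)
  wc <- capillary_work(f_api, config$capillary, wd)
  m_h <- 2 * A$mass * B$mass / (A$mass + B$mass)
  ek <- 0.5 * m_h * e_coag^2 * v_r^2
  ifelse(ek > 0, pmin(1, (wc + wd) / ek), 1)
}

#' Collision efficiency of a granule pair
#'
#' The efficiency is the ratio of the total bridge work (capillary plus
#' viscous) to the pair's kinetic energy `E_k = m e_coag^2 v_r^2 / 2` (with
#' `m` the reduced, harmonic-mean mass), clipped to `[0, 1]`; a pair with no
#' kinetic energy always sticks. The aggregation kernel is
#' `beta = beta0 * beta_star`.
#'
#' @param A,B Granule tuples ([granule_tuple()]).
#' @param config A [granulation_config()].
#' @return `beta_star` in `[0, 1]`.
#' @export
collision_efficiency <- function(A, B, config) {
  mats <- config$materials
  dA <- tuple_derived(A, mats)
  dB <- tuple_derived(B, mats)
  collision_efficiency_vec(c(A, dA), c(B, dB), config)
}

# Vectorised combination rule; A, B as in collision_efficiency_vec, zeta the
# pair deformability. Returns the merged tuple (s1, s2, p, le, li, v) and the
# number of squeeze adjustments.
combine_granules_vec <- function(A, B, zeta) {
  s1 <- A$s1 + B$s1
  s2 <- A$s2 + B$s2
  # external -> internal liquid drawn into the merged pore network
  le_sum <- A$le + B$le
  cap <- (A$v^(1 / 3) + B$v^(1 / 3))
  fA <- 1 - sqrt(pmax(0, 1 - (pmax(0, A$v - A$le))^(1 / 3) / cap))
  fB <- 1 - sqrt(pmax(0, 1 - (pmax(0, B$v - B$le))^(1 / 3) / cap))
  le_to_i <- pmin(le_sum, sqrt(A$le * B$le) * fA * fB)
  le <- le_sum - le_to_i
  li <- A$li + B$li + le_to_i
  # soft (Type II) extreme conserves volume; hard (Type I) conserves area
  v <- zeta * (A$v + B$v) + (1 - zeta) * (A$a + B$a)^(3 / 2) / (6 * sqrt(pi))
  p <- v - s1 - s2 - le
  # squeeze rule: pores must hold the internal liquid. When both parents
  # satisfy li <= p the closure preserves it; the guard catches degenerate
  # inputs by opening the pore space to saturation (li = p).
  bad <- p < li
  n_squeeze <- sum(bad)
  if (any(bad)) {
    v[bad] <- s1[bad] + s2[bad] + le[bad] + li[bad]
    p[bad] <- li[bad]
  }
  p <- pmax(0, p)
  list(s1 = s1, s2 = s2, p = p, le = le, li = li, v = v,
       n_squeeze = n_squeeze)
}

#' Combine two colliding granules
#'
#' Solid volumes are additive. The merged granule volume interpolates between
#' the deformation-driven extreme (`zeta = 1`: volumes, hence pore volumes,
#' are conserved) and the sticking extreme (`zeta = 0`: surface area is
#' conserved, creating additional void): `v = zeta (vA + vB) +
#' (1 - zeta) (aA + aB)^(3/2) / (6 sqrt(pi))`. External liquid is partly
#' drawn into the merged pore network (geometric-mean transfer with
#' overlap-cap factors), and the pore volume closes the volume balance,
#' subject to the squeeze rule (`p >= li`; excess internal liquid is expelled
#' to the surface).
#'
#' @param A,B Granule tuples ([granule_tuple()]).
#' @param zeta Pair deformability in `[0, 1]` (`1 - e_coag`).
#' @return Merged tuple with fields `s1, s2, p, le, li, v`.
#' @export
combine_granules <- function(A, B, zeta) {
  if (any(zeta < 0 | zeta > 1)) {
    abort("zeta must lie in [0, 1]", class = "granupbm_invalid_parameter")
  }
  mats0 <- material_set()  # densities irrelevant for the geometry rule
  dA <- tuple_derived(A, mats0)
  dB <- tuple_derived(B, mats0)
  out <- combine_granules_vec(c(A, dA), c(B, dB), zeta)
  out[c("s1", "s2", "p", "le", "li", "v")]
}

# Full pairwise aggregation rates over the occupied cells, including
# marble-marble aggregation out of the solid-spread class. All quantities are
# rates (per second); the integrator bounds dt so that no cell is over-drawn.
aggregation_rates <- function(state, props, config) {
  beta0 <- config$kinetics$beta0
  out <- list(form = NULL, dep_n = NULL, dep_le = NULL, dep_li = NULL,
              fss_out = 0, n_squeeze = 0L)
  if (beta0 <= 0) return(out)

  pick <- function(P, ix) lapply(P, function(z) z[ix])
  if (!is.null(props)) {
    m <- length(props$cell)
    iA <- rep.int(seq_len(m), rev(seq_len(m)))
    iB <- sequence(rev(seq_len(m)), from = seq_len(m))
    A <- pick(props, iA)
    B <- pick(props, iB)
    bstar <- collision_efficiency_vec(A, B, config)
    self <- iA == iB
    npairs <- ifelse(self, pmax(0, A$n * (A$n - 1) / 2), A$n * B$n)
    rate <- beta0 * bstar * npairs
    keep <- rate > 0
    if (any(keep)) {
      iA <- iA[keep]; iB <- iB[keep]; rate <- rate[keep]
      A <- pick(A, keep); B <- pick(B, keep)
      zeta <- 1 - A$e * B$e
      merged <- combine_granules_vec(A, B, zeta)
      out$n_squeeze <- merged$n_squeeze
      out$form <- list(s1 = merged$s1, s2 = merged$s2, p = merged$p,
                       le_pp = merged$le, li_pp = merged$li, rate = rate)
      # depletion: each event removes one partner from each side cell
      dep <- rowsum(c(rate, rate), group = c(iA, iB), reorder = FALSE)
      ix <- as.integer(rownames(dep))
      dep_n <- numeric(m)
      dep_n[ix] <- dep[, 1]
      out$dep_n <- dep_n
      out$dep_le <- dep_n * props$le
      out$dep_li <- dep_n * props$li
    }
  }

  # marble-marble aggregation into the granule distribution
  if (state$Fss > 1) {
    mats <- config$materials
    g <- granule_tuple(s1 = state$nuclei$v_ss_s1, s2 = 0, p = 0,
                       le = state$nuclei$v_d, li = 0)
    gd <- c(g, tuple_derived(g, mats))
    gl <- lapply(gd, function(z) z)  # single-element vectors
    bstar <- collision_efficiency_vec(gl, gl, config)
    r_ss <- beta0 * bstar * state$Fss * (state$Fss - 1) / 2
    if (r_ss > 0) {
      merged <- combine_granules_vec(gl, gl, 1 - gd$e^2)
      out$fss_out <- 2 * r_ss
      out$form_ss <- list(s1 = merged$s1, s2 = merged$s2, p = merged$p,
                          le_pp = merged$le, li_pp = merged$li, rate = r_ss)
    }
  }
  out
}
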