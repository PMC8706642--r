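#' Nucleation-probability provider
#'
#' The fate of a binder drop hitting the powder bed depends on the
#' formulation's hydrophobicity: wettable beds suck the drop in (immersion
#' nucleation), hydrophobic powder coats the drop into a "liquid marble"
#' (solid-spread nucleation). The probability of immersion, `P_im(f1)`, is
#' supplied by a pluggable provider:
#'
#' * `"logistic"` (default): a logistic curve, monotonically decreasing in the
#'   drug mass fraction, fitted exactly through two anchor points. The default
#'   anchors place `P_im(0.5) = 0.67` (the reported probability at a 50%
#'   hydrophobic-drug formulation) and `P_im(0.4) = 0.95` (solid-spread
#'   formation essentially absent at 40%).
#' * `"constant"`: a fixed value.
#' * `"table"`: linear interpolation through a `(f1, p_im)` table, clamped at
#'   the ends.
#'
#' @param mode `"logistic"`, `"constant"` or `"table"`.
#' @param anchors Two-row data frame / tibble with columns `f1`, `p_im`
#'   (logistic mode), or any number of rows (table mode).
#' @param value Constant probability (constant mode).
#' @return A `nucleation_provider` object, callable as `p(f1)`.
#' @examples
#' p <- nucleation_probability_provider()
#' p(0.5)  # 0.67 by construction
#' @export
nucleation_probability_provider <- function(mode = c("logistic", "constant", "table"),
                                            anchors = data.frame(
                                              f1 = c(0.4, 0.5),
                                              p_im = c(0.95, 0.67)),
                                            value = 1) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (value < 0 || value > 1) {
      abort("constant probability must lie in [0, 1]",
            class = "granupbm_invalid_parameter")
    }
    fn <- function(f1) rep_len(value, length(f1))
  } else {
    if (any(anchors$p_im <= 0) || any(anchors$p_im >= 1)) {
      abort("probability anchors must lie strictly in (0, 1)",
            class = "granupbm_invalid_parameter")
    }
    if (mode == "logistic") {
      stopifnot(nrow(anchors) == 2)
      lg <- log(anchors$p_im / (1 - anchors$p_im))
      k <- -(lg[2] - lg[1]) / (anchors$f1[2] - anchors$f1[1])
      f0 <- anchors$f1[1] + lg[1] / k
      fn <- function(f1) 1 / (1 + exp(k * (f1 - f0)))
    } else {
      af <- anchors$f1
      ap <- anchors$p_im
      fn <- function(f1) approx(af, ap, xout = f1, rule = 2)$y
    }
  }
  structure(fn, class = c("nucleation_provider", "function"), mode = mode)
}

#' Immersion-probability lookup
#'
#' @param f1 Drug mass fraction of the formulation, in `(0, 1)`.
#' @param provider A [nucleation_probability_provider()].
#' @return `P_im` in `[0, 1]`.
#' @export
nucleation_probability <- function(f1, provider) {
  if (any(f1 <= 0 | f1 >= 1)) {
    abort("f1 must lie strictly in (0, 1)", class = "granupbm_invalid_parameter")
  }
  pmin(1, pmax(0, provider(f1)))
}

#' Immersion nucleus volumes at critical packing
#'
#' A drop of volume `v_d` sucks in powder until the liquid occupies the
#' critical-packing fraction `phi_cp` of the nucleus pore space:
#' `v_im = v_d * (1 + (1 - phi_cp)/phi_cp)` and the solid content is
#' `v_im_s = v_d * (1 - phi_cp)/phi_cp`, so `v_im - v_im_s = v_d` always.
#'
#' @param v_d Drop volume (m^3).
#' @param phi_cp Critical-packing liquid volume fraction, `(0, 1)`.
#' @return List with `v_im` (total nucleus volume) and `v_im_s` (solid volume).
#' @export
immersion_nucleus_volumes <- function(v_d, phi_cp) {
  if (phi_cp <= 0 || phi_cp >= 1) {
    abort("phi_cp must lie strictly in (0, 1)",
          class = "granupbm_invalid_parameter")
  }
  list(v_im = v_d * (1 + (1 - phi_cp) / phi_cp),
       v_im_s = v_d * (1 - phi_cp) / phi_cp)
}

#' Solid-spread (liquid marble) nucleus geometry
#'
#' The marble is a drop of diameter `d_d` coated by a shell of drug primary
#' particles of diameter `d_p`: outer diameter `D = d_d + 2 d_p`, total volume
#' `v_ss = pi/6 D^3`, drug shell volume `v_ss_s1 = v_ss - v_d`.
#'
#' @param d_d Drop diameter (m).
#' @param d_p Drug primary particle diameter (m).
#' @return List with `d_ss`, `v_ss`, `v_ss_s1`, `v_d`.
#' @export
solid_spread_nucleus <- function(d_d, d_p) {
  stopifnot(d_d > 0, d_p >= 0)
  d_ss <- d_d + 2 * d_p
  v_ss <- sphere_volume(d_ss)
  v_d <- sphere_volume(d_d)
  list(d_ss = d_ss, v_ss = v_ss, v_ss_s1 = v_ss - v_d, v_d = v_d)
}

# Nucleation rates at the current state. Returns number rates and reservoir
# draw rates; the caller bounds dt and applies them. Drop partitioning is
# exact: n_im + n_ss = q_nuc / v_d before any mass capping.
nucleation_rates <- function(state, config, q_nuc) {
  mats <- config$materials
  v_d <- state$nuclei$v_d
  p_im <- nucleation_probability(mats$f1, config$nucleation)
  n_im <- p_im * q_nuc / v_d
  n_ss <- (1 - p_im) * q_nuc / v_d

  imv <- immersion_nucleus_volumes(v_d, mats$phi_cp)
  # powder-bed composition as volume fractions (mass fractions over densities)
  vol1 <- state$Ms1 / mats$rho_s1
  vol2 <- state$Ms2 / mats$rho_s2
  if (vol1 + vol2 <= 0) {
    return(list(n_im = 0, n_ss = 0, s1_im = 0, s2_im = 0,
                dMs1 = 0, dMs2 = 0, v_im = imv$v_im, v_im_s = imv$v_im_s))
  }
  fv1 <- vol1 / (vol1 + vol2)
  if (fv1 < 1e-6) {
    # drug powder (essentially) exhausted: marbles cannot form, remaining
    # drops immerse into the excipient-only bed
    n_im <- n_im + n_ss
    n_ss <- 0
  }
  s1_im <- fv1 * imv$v_im_s          # drug volume per immersion nucleus
  s2_im <- (1 - fv1) * imv$v_im_s
  dMs1 <- n_im * s1_im * mats$rho_s1 + n_ss * state$nuclei$v_ss_s1 * mats$rho_s1
  dMs2 <- n_im * s2_im * mats$rho_s2
  list(n_im = n_im, n_ss = n_ss, s1_im = s1_im, s2_im = s2_im,
       dMs1 = dMs1, dMs2 = dMs2, v_im = imv$v_im, v_im_s = imv$v_im_s)
}
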