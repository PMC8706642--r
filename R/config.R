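#' Physical properties of the formulation and binder
#'
#' Bundles the material constants used by every rate law. Defaults describe an
#' ibuprofen / microcrystalline-cellulose formulation granulated with an
#' aqueous polymeric binder: the restitution coefficients are the calibrated
#' values for that system, the critical-packing liquid fraction is 0.2, and
#' the remaining properties are handbook-scale values.
#'
#' @param rho_s1,rho_s2 True densities of drug and excipient (kg/m^3).
#' @param e_s1,e_s2 Coefficients of restitution of drug and excipient, in
#'   `[0, 1]` (0 = fully plastic, 1 = fully elastic).
#' @param mu Binder viscosity (Pa s).
#' @param sigma Binder surface tension (N/m).
#' @param rho_l Binder density (kg/m^3).
#' @param d_p Drug primary particle diameter (m).
#' @param d_p2 Excipient primary particle diameter (m).
#' @param f1 Drug mass fraction of the formulation, in `(0, 1)`.
#' @param phi_cp Critical-packing liquid volume fraction of an immersion
#'   nucleus (dimensionless, `(0, 1)`).
#' @param eps_min Minimum granule porosity reachable by consolidation.
#' @param h_a Granule surface asperity height (m); viscous bridge work
#'   vanishes when the binder layer is thinner than this.
#' @return A `material_set` list.
#' @export
material_set <- function(rho_s1 = 1100, rho_s2 = 1540,
                         e_s1 = 0.162, e_s2 = 0.07,
                         mu = 0.001, sigma = 0.07, rho_l = 1000,
                         d_p = 50e-6, d_p2 = 65e-6,
                         f1 = 0.5, phi_cp = 0.2, eps_min = 0.1,
                         h_a = 1e-6) {
  if (phi_cp <= 0 || phi_cp >= 1) {
    abort("phi_cp must lie strictly in (0, 1)", class = "granupbm_invalid_parameter")
  }
  if (e_s1 < 0 || e_s1 > 1 || e_s2 < 0 || e_s2 > 1) {
    abort("restitution coefficients must lie in [0, 1]",
          class = "granupbm_invalid_parameter")
  }
  if (f1 <= 0 || f1 >= 1) {
    abort("f1 must lie strictly in (0, 1)", class = "granupbm_invalid_parameter")
  }
  stopifnot(rho_s1 > 0, rho_s2 > 0, rho_l > 0, mu > 0, sigma > 0,
            d_p > 0, d_p2 > 0, eps_min >= 0, eps_min < 1, h_a > 0)
  structure(
    list(rho_s1 = rho_s1, rho_s2 = rho_s2, e_s1 = e_s1, e_s2 = e_s2,
         mu = mu, sigma = sigma, rho_l = rho_l, d_p = d_p, d_p2 = d_p2,
         f1 = f1, phi_cp = phi_cp, eps_min = eps_min, h_a = h_a),
    class = "material_set"
  )
}

#' Operating conditions of the granulation run
#'
#' @param charge_mass Total initial powder charge (kg).
#' @param ls_ratio Liquid-to-solid mass ratio; the binder volume sprayed is
#'   `ls_ratio * charge_mass / rho_l`.
#' @param q_spray Volumetric binder spray rate (m^3/s).
#' @param d_d Binder drop diameter (m); the single-drop volume is
#'   `pi/6 * d_d^3`.
#' @param gamma Characteristic shear rate in the granulator (1/s).
#' @param phi_p Particle volume fraction in the granulator, `(0, 1)`.
#' @param t_end Total simulated time (s); must be at least the spray duration.
#' @param rho_l Binder density used to convert the liquid-to-solid mass ratio
#'   into a volume (kg/m^3); kept here so the duration invariant is
#'   self-contained.
#' @return A `process_conditions` list with the derived `v_d` (drop volume)
#'   and `spray_time` (s).
#' @export
process_conditions <- function(charge_mass = 2, ls_ratio = 0.6,
                               q_spray = 2e-5, d_d = 4e-4,
                               gamma = 1000, phi_p = 0.3,
                               t_end = 120, rho_l = 1000) {
  stopifnot(charge_mass > 0, ls_ratio > 0, q_spray > 0, d_d > 0,
            gamma > 0, t_end > 0)
  if (phi_p <= 0 || phi_p >= 1) {
    abort("phi_p must lie strictly in (0, 1)", class = "granupbm_invalid_parameter")
  }
  spray_time <- ls_ratio * charge_mass / (rho_l * q_spray)
  if (spray_time > t_end + 1e-9) {
    abort(sprintf(
      "spray duration (%.3g s) exceeds t_end (%.3g s)", spray_time, t_end),
      class = "granupbm_invalid_parameter")
  }
  structure(
    list(charge_mass = charge_mass, ls_ratio = ls_ratio, q_spray = q_spray,
         d_d = d_d, v_d = sphere_volume(d_d), gamma = gamma, phi_p = phi_p,
         t_end = t_end, spray_time = spray_time),
    class = "process_conditions"
  )
}

#' Capillary-number regression
#'
#' The collision-efficiency kernel scales the capillary work by a
#' formulation-dependent capillary number `Ca(f)` (ratio of capillary to
#' viscous bridge force) evaluated at the pair's drug solid fraction. The
#' regression is log-linear through two anchor points, which it reproduces
#' exactly; negative user coefficients are clipped to zero with a warning.
#'
#' @param f Anchor drug fractions (length 2).
#' @param ca Capillary numbers at the anchors (length 2, positive).
#' @return A function `Ca(f)`.
#' @export
capillary_number_model <- function(f = c(0.2, 0.8), ca = c(0.5, 2)) {
  stopifnot(length(f) == 2, length(ca) == 2, f[1] != f[2])
  if (any(ca <= 0)) {
    abort("capillary-number anchors must be positive",
          class = "granupbm_invalid_parameter")
  }
  b <- (log(ca[2]) - log(ca[1])) / (f[2] - f[1])
  a <- log(ca[1]) - b * f[1]
  function(x) {
    out <- exp(a + b * x)
    if (any(!is.finite(out) | out < 0)) {
      warn("capillary number clipped to 0")
      out <- pmax(0, out)
      out[!is.finite(out)] <- 0
    }
    out
  }
}

#' Assemble a full simulation configuration
#'
#' Collects materials, process conditions, grid/time-step numerics, the six
#' kinetic constants, the nucleation-probability provider, the
#' capillary-number model and the breakage block into one validated list.
#' Defaults are the package's reference study conditions: the calibrated
#' kinetic constants (`beta0 = 4.34e-10`, `k_con = 1.67e-3`,
#' `k_layer = 2.01e-8`, `k_sg = 4.59e-11`) on a 12-bin-per-coordinate grid
#' spanning 31.5 um to 6 mm.
#'
#' @param materials A [material_set()].
#' @param process A [process_conditions()].
#' @param numerics List: `base_diameter`, `max_diameter`, `n_bins`,
#'   `ratio_mode`, `dt_max`, `dt_min`, `safety`, `record_every` (s).
#' @param kinetics List of rate constants: `beta0` (aggregation, 1/(pair s)),
#'   `k_con` (consolidation, 1/m), `k_layer` (layering, 1/(m^2 s)),
#'   `k_sg` (surface growth, m/s per marble).
#' @param nucleation A [nucleation_probability_provider()].
#' @param capillary A function `Ca(f)` as from [capillary_number_model()].
#' @param breakage List: `enabled`, `p_brk`, `size_exponent`, `daughter_rule`
#'   (`"equal_halves"` or `"uneven"`), `theta`.
#' @param kernel_override `NULL` for the physics-based efficiency, or
#'   `"constant"` to force the collision efficiency to 1 (oracle runs).
#' @param spray_split `"bed_fraction"`: a fraction of spray equal to the
#'   remaining un-granulated powder fraction nucleates and the rest rewets
#'   granule surfaces; `"all_nucleation"`: every drop nucleates.
#' @return A `granulation_config` list.
#' @export
granulation_config <- function(materials = material_set(),
                               process = NULL,
                               numerics = list(),
                               kinetics = list(),
                               nucleation = nucleation_probability_provider(),
                               capillary = capillary_number_model(),
                               breakage = list(),
                               kernel_override = NULL,
                               spray_split = c("bed_fraction", "all_nucleation")) {
  spray_split <- match.arg(spray_split)
  if (is.null(process)) {
    process <- process_conditions(rho_l = materials$rho_l)
  }
  num <- modify_defaults(
    list(base_diameter = 31.5e-6, max_diameter = 6000e-6, n_bins = 12L,
         ratio_mode = "fit_span", dt_max = 0.1, dt_min = 1e-5, safety = 0.5,
         record_every = 5),
    numerics
  )
  kin <- modify_defaults(
    list(beta0 = 4.34e-10, k_con = 1.67e-3, k_layer = 2.01e-8,
         k_sg = 4.59e-11),
    kinetics
  )
  stopifnot(kin$beta0 >= 0, kin$k_con >= 0, kin$k_layer >= 0, kin$k_sg >= 0)
  brk <- modify_defaults(
    list(enabled = FALSE, p_brk = 0, size_exponent = 1,
         daughter_rule = "equal_halves", theta = 0.5),
    breakage
  )
  structure(
    list(materials = materials, process = process, numerics = num,
         kinetics = kin, nucleation = nucleation, capillary = capillary,
         breakage = brk, kernel_override = kernel_override,
         spray_split = spray_split),
    class = "granulation_config"
  )
}

modify_defaults <- function(defaults, user) {
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown option(s): ", paste(unknown, collapse = ", ")),
          class = "granupbm_invalid_parameter")
  }
  defaults[names(user)] <- user
  defaults
}

#' Override a tunable parameter in a configuration
#'
#' Resolves the six calibrated constants by name (`beta0`, `e_s1`, `e_s2`,
#' `k_con`, `k_layer`, `k_sg`) to their home in the configuration and returns
#' the modified configuration. Used by the sensitivity scan and the
#' calibration objectives.
#'
#' @param config A `granulation_config`.
#' @param name Parameter name.
#' @param value New value.
#' @return The modified configuration.
#' @export
set_config_parameter <- function(config, name, value) {
  kin <- c("beta0", "k_con", "k_layer", "k_sg")
  mat <- c("e_s1", "e_s2", "f1", "mu", "sigma", "phi_cp", "eps_min", "h_a")
  if (name %in% kin) {
    config$kinetics[[name]] <- value
  } else if (name %in% mat) {
    config$materials[[name]] <- value
  } else {
    abort(paste0("unknown tunable parameter: ", name),
          class = "granupbm_invalid_parameter")
  }
  config
}

#' Fetch a tunable parameter from a configuration
#' @inheritParams set_config_parameter
#' @return The current value.
#' @export
get_config_parameter <- function(config, name) {
  if (name %in% names(config$kinetics)) return(config$kinetics[[name]])
  if (name %in% names(config$materials)) return(config$materials[[name]])
  abort(paste0("unknown tunable parameter: ", name),
        class = "granupbm_invalid_parameter")
}
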