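#' Build the geometric volume grid for the internal coordinates
#'
#' Each internal coordinate (drug volume `s1`, excipient volume `s2`, pore
#' volume `p`) is discretized on the same geometric grid of sphere-equivalent
#' volumes, `v_i = v_base * ratio^(i-1)`. Two modes are supported:
#'
#' * `"fit_span"` (default): the ratio is chosen as
#'   `(v_max / v_base)^(1/(n_bins - 1))` so that bin `n_bins` lands exactly on
#'   `max_diameter`. This honours the physically meaningful size window.
#' * `"fixed_ratio_4"`: a fixed volume ratio of 4 between adjacent bins,
#'   regardless of `max_diameter`.
#'
#' An implicit zero node is prepended when the grid is used by the ensemble,
#' so coordinates may take the value 0 (e.g. granules with no drug content).
#'
#' @param base_diameter Sphere-equivalent diameter (m) of the smallest bin.
#' @param max_diameter Sphere-equivalent diameter (m) of the largest bin
#'   (used by `fit_span`).
#' @param n_bins Number of bins per coordinate (>= 2).
#' @param ratio_mode `"fit_span"` or `"fixed_ratio_4"`.
#' @return A `volume_grid` object: list with `base_volume`, `ratio`, `n_bins`,
#'   `volumes` (representative volumes, m^3), `diameters` (m) and `nodes`
#'   (volumes with the zero node prepended).
#' @examples
#' g <- build_grid(31.5e-6, 6000e-6, 20)
#' g$ratio                      # ~2.291 for the 20-bin span
#' tail(g$diameters, 1)         # 6 mm by construction
#' @export
build_grid <- function(base_diameter, max_diameter, n_bins,
                       ratio_mode = c("fit_span", "fixed_ratio_4")) {
  ratio_mode <- match.arg(ratio_mode)
  if (!is.numeric(base_diameter) || base_diameter <= 0 ||
      !is.numeric(max_diameter) || max_diameter <= 0) {
    abort("grid diameters must be positive", class = "granupbm_invalid_parameter")
  }
  if (n_bins < 2) {
    abort("n_bins must be >= 2", class = "granupbm_invalid_parameter")
  }
  if (base_diameter >= max_diameter) {
    abort("base_diameter must be smaller than max_diameter",
          class = "granupbm_invalid_parameter")
  }
  v_base <- sphere_volume(base_diameter)
  v_max <- sphere_volume(max_diameter)
  ratio <- switch(ratio_mode,
    fit_span = (v_max / v_base)^(1 / (n_bins - 1)),
    fixed_ratio_4 = 4
  )
  volumes <- v_base * ratio^(seq_len(n_bins) - 1)
  structure(
    list(
      base_volume = v_base,
      ratio = ratio,
      n_bins = as.integer(n_bins),
      volumes = volumes,
      diameters = sphere_diameter(volumes),
      nodes = c(0, volumes)
    ),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d bins/coordinate, d = %.1f um .. %.0f um (volume ratio %.3f)\n",
    x$n_bins, 1e6 * x$diameters[1], 1e6 * tail(x$diameters, 1), x$ratio
  ))
  invisible(x)
}

sphere_volume <- function(d) pi / 6 * d^3

sphere_diameter <- function(v) (6 * v / pi)^(1 / 3)

#' Total granule volume
#'
#' The granule volume is the sum of the drug solid volume, excipient solid
#' volume, external (surface) liquid volume and pore volume. Internal liquid
#' resides inside the pores and does not add volume.
#'
#' @param s1,s2,le,p Component volumes (m^3), vectorised.
#' @return Total volume (m^3).
#' @export
granule_volume <- function(s1, s2, le, p) {
  if (any(s1 < 0 | s2 < 0 | le < 0 | p < 0)) {
    abort("granule component volumes must be non-negative",
          class = "granupbm_invalid_state")
  }
  s1 + s2 + le + p
}

#' Sphere-equivalent surface area of a granule
#'
#' `a = pi^(1/3) * (6 v)^(2/3)`, i.e. the surface area of a sphere with the
#' granule's total volume.
#'
#' @param v Granule volume (m^3), vectorised.
#' @return Surface area (m^2).
#' @export
surface_area <- function(v) {
  if (any(v < 0)) {
    abort("volume must be non-negative", class = "granupbm_invalid_state")
  }
  pi^(1 / 3) * (6 * v)^(2 / 3)
}

#' Granule porosity and drug content
#'
#' Porosity is the pore volume fraction `eps = p / v`; the content coordinate
#' is the drug volume fraction `q = s1 / v`, both relative to the total
#' granule volume.
#'
#' @inheritParams granule_volume
#' @return A list with `porosity` and `content`, each in `[0, 1]`.
#' @export
porosity_and_content <- function(s1, s2, le, p) {
  v <- granule_volume(s1, s2, le, p)
  if (any(v <= 0)) {
    abort("granule volume must be positive to define porosity/content",
          class = "granupbm_undefined_property")
  }
  list(porosity = p / v, content = s1 / v)
}
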