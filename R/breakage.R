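#' Shear-driven binary breakage rates
#'
#' Granules break at a shear-proportional rate
#' `K = p_brk * gamma * d^size_exponent`; each event removes one parent and
#' deposits two daughters whose internal coordinates and attached liquid are
#' the parent's split in fixed proportions (`theta`, `1 - theta`; equal
#' halves by default), so every coordinate is conserved exactly. The model is
#' off by default (`p_brk = 0`).
#'
#' @param props Occupied-cell properties from `cell_properties()`.
#' @param state The `granulation_state`.
#' @param config A [granulation_config()] with a `breakage` block.
#' @return `NULL` when inactive, else a list with per-cell parent removal
#'   rate `dep_n` and daughter parcel targets (coordinates, number rate and
#'   per-particle liquid).
#' @keywords internal
breakage_rates <- function(props, state, config) {
  brk <- config$breakage
  if (is.null(props) || !isTRUE(brk$enabled) || brk$p_brk <= 0) return(NULL)
  gamma <- config$process$gamma
  k <- brk$p_brk * gamma * props$d^brk$size_exponent
  theta <- if (identical(brk$daughter_rule, "equal_halves")) 0.5 else brk$theta
  stopifnot(theta > 0, theta < 1)
  rate <- k * props$n
  frac <- c(theta, 1 - theta)
  list(
    dep_n = rate,
    form = list(
      s1 = c(props$s1 * frac[1], props$s1 * frac[2]),
      s2 = c(props$s2 * frac[1], props$s2 * frac[2]),
      p = c(props$p * frac[1], props$p * frac[2]),
      le_pp = c(props$le * frac[1], props$le * frac[2]),
      li_pp = c(props$li * frac[1], props$li * frac[2]),
      rate = c(rate, rate)
    )
  )
}
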