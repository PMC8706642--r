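#' Plot methods
#'
#' `autoplot()` on a `granulation_record` shows the evolution of d10/d50/d90;
#' on a `granulation_sensitivity` a bar chart of sensitivities per parameter;
#' on a `granulation_calibration` the Pareto front. `plot_csd()` draws the
#' final cumulative size distribution of one or more records.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name granupbm_plots
NULL

#' @rdname granupbm_plots
#' @method autoplot granulation_record
#' @export
autoplot.granulation_record <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$series, "time", "d10", "d50", "d90"),
    -"time", names_to = "quantile", values_to = "diameter"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$diameter * 1e6,
                                   colour = .data$quantile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "diameter (µm)", colour = NULL)
}

#' @rdname granupbm_plots
#' @param records A named list of `granulation_record`s.
#' @export
plot_csd <- function(records, ...) {
  if (inherits(records, "granulation_record")) records <- list(run = records)
  df <- dplyr::bind_rows(lapply(records, function(r) {
    size_statistics(r$final_state, r$config$materials)$curve
  }), .id = "run")
  ggplot2::ggplot(df, ggplot2::aes(.data$diameter * 1e6, .data$cum_vol_frac,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "diameter (µm)", y = "cumulative volume fraction",
                  colour = NULL)
}

#' @rdname granupbm_plots
#' @method autoplot granulation_sensitivity
#' @export
autoplot.granulation_sensitivity <- function(object, ...) {
  df <- tidyr::pivot_longer(object, -c("parameter", "perturbation"),
                            names_to = "output", values_to = "sensitivity")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$perturbation),
                                   .data$sensitivity,
                                   fill = .data$parameter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~output, scales = "free_y") +
    ggplot2::labs(x = "perturbation", y = "(Y0 - Yi)/Y0", fill = NULL)
}

#' @rdname granupbm_plots
#' @method autoplot granulation_calibration
#' @export
autoplot.granulation_calibration <- function(object, ...) {
  ggplot2::ggplot(object$members,
                  ggplot2::aes(.data$sse_size, .data$sse_content)) +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = object$compromise, colour = "red", size = 3) +
    ggplot2::labs(x = "SSE (size)", y = "SSE (content)")
}
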