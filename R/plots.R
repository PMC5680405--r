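#' Plot a concentration profile
#'
#' Normalised concentration against radius, one line per stored time,
#' faceted by phase when both infusion and post-infusion slices are
#' present.
#'
#' @param object A `ced_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ced_profile
#' @export
autoplot.ced_profile <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(.data$radius_cm, .data$c_norm,
                 colour = factor(signif(.data$time_h, 4)))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from catheter tip (cm)",
                  y = expression(C[norm]),
                  colour = "Time (h)") +
    ggplot2::theme_minimal()
  if (length(unique(object$phase)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$phase))
  }
  p
}

#' Plot a rate-comparison experiment
#'
#' End-of-infusion concentration profiles for each infusion rate, from
#' the output of [run_rate_comparison()] (run with
#' `keep_profiles = TRUE`).
#'
#' @param x The list returned by [run_rate_comparison()].
#' @return A ggplot object.
#' @export
plot_rate_comparison <- function(x) {
  if (is.null(x$profiles)) {
    abort("Run `run_rate_comparison()` with `keep_profiles = TRUE` to plot.",
          class = "cedflow_invalid_parameter")
  }
  ggplot2::ggplot(
    x$profiles,
    ggplot2::aes(.data$radius_cm, .data$c_norm,
                 colour = factor(.data$rate_ul_min))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from catheter tip (cm)",
                  y = expression(C[norm]),
                  colour = "Rate (uL/min)",
                  title = "End-of-infusion profiles by infusion rate") +
    ggplot2::theme_minimal()
}
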