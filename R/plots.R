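# ggplot2 autoplot methods for the package's result objects.

#' Plot a lagged cross-correlation profile with its null envelope
#'
#' @param object A `lag_profile` from [classify_lagged_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lag_profile
#' @export
autoplot.lag_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_lower,
                                      ymax = .data$null_upper),
                         fill = "grey80", alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$statistic)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(
      data = df[df$lag == attr(object, "strongest_lag"), ],
      ggplot2::aes(y = .data$statistic), colour = "red") +
    ggplot2::labs(x = "lag (months; negative = x leads)",
                  y = "Pearson r",
                  title = "Cross-correlation vs red-noise envelope") +
    ggplot2::theme_minimal()
}

#' Plot cross-map skill against the prediction offset
#'
#' @param object A `ccm_lag_profile` from [lagged_ccm()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ccm_lag_profile
#' @export
autoplot.ccm_lag_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tp, y = .data$skill)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = attr(object, "null_q95"),
                        linetype = "dotted", colour = "red") +
    ggplot2::geom_point(data = df[df$tp == attr(object, "optimal_tp"), ],
                        colour = "red") +
    ggplot2::labs(x = "prediction offset tp (months)",
                  y = "cross-map skill (rho)",
                  title = attr(object, "direction")) +
    ggplot2::theme_minimal()
}

#' Plot a convergence (skill vs library size) curve
#'
#' @param object A `ccm_fit` from [ccm_skill()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ccm_fit
#' @export
autoplot.ccm_fit <- function(object, ...) {
  ggplot2::ggplot(object$skills,
                  ggplot2::aes(x = .data$library_size, y = .data$skill)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "library size", y = "cross-map skill (rho)",
                  title = object$direction,
                  subtitle = sprintf("E = %d, tp = %+d, convergent: %s",
                                     object$E, object$tp,
                                     format(object$convergent))) +
    ggplot2::theme_minimal()
}

#' Plot the five state-metric series
#'
#' @param object A `state_metric_set` from [state_metrics()].
#' @param ... Unused.
#' @return A faceted ggplot.
#' @method autoplot state_metric_set
#' @export
autoplot.state_metric_set <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"month",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "System state metrics") +
    ggplot2::theme_minimal()
}

#' Plot the three functional diversity series of a guild
#'
#' @param object An `fd_series` from [fd_series()].
#' @param ... Unused.
#' @return A faceted ggplot.
#' @method autoplot fd_series
#' @export
autoplot.fd_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"month",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$month, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Functional diversity",
                                attr(object, "guild") %||% "")) +
    ggplot2::theme_minimal()
}
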