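#' Plot a simulated course
#'
#' Log-scale concentration-time curves for the global plasma,
#' interstitial and intracellular compartments, with an optional
#' concentration floor.
#'
#' @param object An `mtx_sim` from [simulate_course()].
#' @param units Concentration units for the y axis.
#' @param floor Concentrations below this (in `units`) are not drawn.
#' @param config Model configuration (unit conversion).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtx_sim <- function(object, units = "umol/L", floor = 1e-4,
                             config = load_config(), ...) {
  df <- tidy(object)
  df <- df[df$compartment %in% c("cs", "isf", "icf"), ]
  df$conc <- convert_concentration(df$conc_mg_per_ml, "mg/mL", units,
                                   config)
  df <- df[df$conc > floor, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 60, y = .data$conc,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = paste0("concentration (", units, ")"),
                  colour = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted concentrations for a fit
#'
#' @param object An `mtx_fit` from [fit_population()].
#' @param units Concentration units for both axes.
#' @param config Model configuration.
#' @param ... Unused.
#' @return A ggplot object (log-log scatter with the identity line).
#' @export
autoplot.mtx_fit <- function(object, units = "umol/L",
                             config = load_config(), ...) {
  df <- object$predictions
  df$obs <- convert_concentration(df$observed, "mg/mL", units, config)
  df$pred <- convert_concentration(df$predicted, "mg/mL", units, config)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$obs, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0("observed (", units, ")"),
                  y = paste0("predicted (", units, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap resampling distributions
#'
#' @param object An `mtx_boot` from [bootstrap_population()].
#' @param ... Unused.
#' @return A ggplot object (one histogram panel per parameter).
#' @export
autoplot.mtx_boot <- function(object, ...) {
  df <- tidyr::pivot_longer(object$samples, dplyr::all_of(pop_names),
                            names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "resamples") +
    ggplot2::theme_minimal()
}
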