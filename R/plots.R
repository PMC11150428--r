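#' Plot simulated abundance trajectories
#'
#' Yearly adult abundance per sex and total population size for one
#' simulated population history.
#'
#' @param object A `ckmr_sim` object from [simulate_population()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckmr_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$truth, -"year",
                              names_to = "series", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(.data$year, .data$abundance,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Individuals",
                  title = sprintf("Simulated '%s' population",
                                  object$species$name)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted abundance estimate with its confidence interval
#'
#' @param object A `ckmr_fit` object from [fit_ckmr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ckmr_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$term, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "Adult abundance",
                  title = "CKMR abundance estimates (95% log-normal CI)") +
    ggplot2::theme_minimal()
}

#' Box plots of relative estimation error across scenarios
#'
#' Mirrors the usual presentation of misspecification sweeps: one box per
#' scenario and sex of the replicate-level relative errors
#' `100 (estimate - N_true) / N_true`, with non-converged fits dropped and
#' excluded scenarios (mostly-failed cells) left blank.
#'
#' @param fits A tibble from [run_scenario_grid()].
#' @param threshold Exclusion threshold, see [apply_exclusion_rule()].
#' @return A ggplot object.
#' @export
plot_scenario_errors <- function(fits, threshold = 0.5) {
  excl <- apply_exclusion_rule(fits, threshold)
  keep <- excl$scenario[!excl$excluded]
  d <- dplyr::filter(fits, .data$converged, .data$scenario %in% keep)
  d <- dplyr::mutate(d, rel_error = 100 * (.data$estimate - .data$N_true) /
                       .data$N_true)
  ggplot2::ggplot(d, ggplot2::aes(.data$scenario, .data$rel_error,
                                  fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Scenario", y = "Relative error (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
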