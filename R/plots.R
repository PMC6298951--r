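#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an HRTF set
#'
#' Log-amplitude spectra as a function of log-frequency, one curve per
#' elevation, the conventional way measured HRTF sets are displayed.
#'
#' @param object An `hrtf_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hrtf_set <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$freq_hz, y = .data$gain_db,
                                 group = .data$elevation_deg,
                                 colour = .data$elevation_deg)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_viridis_c(name = "elevation (deg)") +
    ggplot2::labs(x = "frequency (Hz)", y = "gain (dB)") +
    ggplot2::theme_minimal()
}

#' Plot a posterior curve
#'
#' Correlation function, rectified likelihood and posterior over the template
#' elevation grid for a single trial.
#'
#' @param object A `posterior_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posterior_curve <- function(object, ...) {
  tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("correlation", "likelihood", "posterior"),
                        names_to = "curve", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$elevation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "elevation (deg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stimulus-response scatter of a session
#'
#' Elevation responses against targets, one panel per stimulus kind, with the
#' identity diagonal (veridical behaviour) and the fitted regression line.
#'
#' @param data Trial tibble.
#' @return A ggplot.
#' @export
plot_session <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$target_el_deg,
                                     y = .data$resp_el_deg)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~stim_kind) +
    ggplot2::labs(x = "target elevation (deg)", y = "response elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Windowed learning curves
#'
#' Gain, r^2 and MAE of the windowed stimulus-response regression as a
#' function of window start trial: the within-session learning curve.
#'
#' @param windowed Tibble from [windowed_regression()].
#' @return A ggplot.
#' @export
plot_learning_curve <- function(windowed) {
  windowed |>
    dplyr::select(dplyr::all_of(c("start", "gain", "r2", "mae"))) |>
    tidyr::pivot_longer(-"start", names_to = "measure", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window start (trial)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Spectral-weight trajectory
#'
#' Weight profiles over training, coloured by trial, showing which frequency
#' bands the learning rule boosts.
#'
#' @param snapshots Tibble of weight snapshots (`trial`, `freq_hz`, `weight`),
#'   as recorded by [simulate_training_session()].
#' @return A ggplot.
#' @export
plot_weight_trajectory <- function(snapshots) {
  ggplot2::ggplot(snapshots, ggplot2::aes(x = .data$freq_hz, y = .data$weight,
                                          group = .data$trial,
                                          colour = .data$trial)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_viridis_c(name = "trial") +
    ggplot2::labs(x = "frequency (Hz)", y = "weight") +
    ggplot2::theme_minimal()
}
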