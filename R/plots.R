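# ggplot2 displays for the two result types: sample-size deviation curves
# and the per-draw variability relationships.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sample-size deviation curves
#'
#' Deviation of the sample SD from the full-data SD against the number of
#' individuals sampled, one panel per trait, one line per species. The
#' characteristic shape is a steep drop up to about 20 individuals and a
#' flatter tail beyond.
#'
#' @param object A `callvar_curve` tibble from [curve_study()] (or a
#'   single-species [sample_size_curve()] result with a `species` column
#'   added).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot callvar_curve
#' @export
autoplot.callvar_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("deviation_duration", "deviation_freq"),
    names_to = "trait", values_to = "deviation",
    names_prefix = "deviation_"
  )
  long$trait <- c(duration = "call duration (s)",
                  freq = "peak frequency (Hz)")[long$trait]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n, y = .data$deviation, colour = .data$species
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(
      x = "individuals in sample (N)",
      y = "deviation of sample SD from population SD",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.callvar_curve
#' @export
plot_sample_size_curve <- function(object, ...) autoplot.callvar_curve(object, ...)

#' Plot resampled variability against area and day span
#'
#' Scatter of the z-scored per-draw SDs against the z-scored hull area and
#' intra-annual day span, with per-species OLS lines — the per-draw view
#' behind the species models.
#'
#' @param z_samples Output of [zscore_within_species()].
#' @return A ggplot, faceted trait x predictor.
#' @export
plot_variability_relationships <- function(z_samples) {
  long <- tibble::as_tibble(z_samples) |>
    tidyr::pivot_longer(c("z_sd_duration", "z_sd_freq"),
                        names_to = "trait", values_to = "z_sd") |>
    tidyr::pivot_longer(c("z_area", "z_span"),
                        names_to = "predictor", values_to = "z_x")
  long$trait <- c(z_sd_duration = "SD call duration (z)",
                  z_sd_freq = "SD peak frequency (z)")[long$trait]
  long$predictor <- c(z_area = "hull area (z)",
                      z_span = "day span (z)")[long$predictor]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$z_x, y = .data$z_sd, colour = .data$species
  )) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
    ggplot2::facet_grid(trait ~ predictor) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
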