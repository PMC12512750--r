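# ggplot2 views of the pipeline's result types.

#' Plot the sweeps of a trial coloured by pressure
#'
#' @param trial An `icp_trial` (aligned trials colour by reference
#'   pressure; unaligned by sweep time).
#' @param channel Which channel to draw.
#' @param every Draw every `every`-th sweep to keep the plot light.
#' @return A ggplot.
#' @export
plot_sweeps <- function(trial, channel = c("sxx_mag", "sxy_mag",
                                           "sxx_phase", "sxy_phase"),
                        every = 10) {
  channel <- match.arg(channel)
  df <- as_tibble(trial)
  keep <- unique(c(seq(1, nrow(trial[[channel]]), by = every),
                   nrow(trial[[channel]])))
  df <- df[df$sweep_index %in% keep, ]
  ycol <- c(sxx_mag = "sxx_mag_db", sxy_mag = "sxy_mag_db",
            sxx_phase = "sxx_phase_rad", sxy_phase = "sxy_phase_rad")[[channel]]
  colour <- if ("p_mmHg" %in% names(df)) "p_mmHg" else "time_s"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_GHz, y = .data[[ycol]],
                                   group = .data$sweep_index,
                                   colour = .data[[colour]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (GHz)", y = ycol,
                  colour = if (colour == "p_mmHg") "p (mmHg)" else "t (s)",
                  title = sprintf("Sensor %s, trial %d", trial$sensor_id,
                                  trial$trial_index)) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap (feature class vs dataset variant)
#'
#' @param object An `icp_corr` from [correlate_features()].
#' @param ... Unused.
#' @return A ggplot tile map of mean r per (class, variant).
#' @export
autoplot.icp_corr <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$class, .data$variant) |>
    dplyr::summarise(r = mean(.data$r), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$class,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "Dataset variant", y = "Feature class",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-true and residual view of an evaluation report
#'
#' @param object An `icp_eval` from [evaluate_models()].
#' @param presets Preset ids to include (default: best by RMSE).
#' @param truth True pressures of the evaluated rows (mmHg); taken from the
#'   residuals when omitted.
#' @param ... Unused.
#' @return A ggplot of predicted vs true pressure.
#' @export
autoplot.icp_eval <- function(object, presets = NULL, truth = NULL, ...) {
  if (is.null(presets)) presets <- select_best(object)
  df <- object[object$preset_id %in% presets, ]
  long <- purrr::pmap_dfr(
    list(df$preset_id, df$predicted, df$residuals),
    function(pid, pred, resid) {
      tibble::tibble(preset_id = pid, predicted = pred,
                     true = pred - resid)
    })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~preset_id) +
    ggplot2::labs(x = "Reference pressure (mmHg)",
                  y = "Predicted pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
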