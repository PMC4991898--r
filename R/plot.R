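#' Plot a raw recording
#'
#' Time series of each channel, faceted, for a quick visual check of the
#' signal and its burst structure.
#'
#' @param object An [emg_recording()].
#' @param max_seconds Plot at most this many seconds from the start.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_recording <- function(object, max_seconds = 5, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$time <= min(max(.data$time), max_seconds)) |>
    tidyr::pivot_longer(-"time", names_to = "channel",
                        values_to = "amplitude") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = canonical_channels()))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), ncol = 2,
                        scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (mV)")
}

#' Plot ensemble activation curves
#'
#' Mean +/- SD ribbon of each muscle's ensemble curve over the gait cycle,
#' left and right overlaid -- the per-muscle activation profile view.
#'
#' @param object An `emg_ensemble` tibble (see [ensemble_average()] or
#'   [report_ensembles()]); a `speed` column, if present, becomes facet
#'   columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_ensemble <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(muscle = factor(.data$muscle, levels = emg_muscles()))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$mean,
                                        colour = .data$side,
                                        fill = .data$side)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gait-cycle phase", y = "Activation (%MVC)",
                  colour = "Side", fill = "Side")
  if ("speed" %in% names(df)) {
    p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$muscle),
      cols = ggplot2::vars(.data$speed), scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$muscle), scales = "free_y")
  }
}

#' Plot an asymmetry report
#'
#' For dynamic reports: per-muscle mean %MVC against treadmill speed, one
#' line per side, significant left/right differences marked with an
#' asterisk. For static reports: side-by-side bars per muscle.
#'
#' @param object An `asymmetry_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asymmetry_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(muscle = factor(.data$muscle, levels = emg_muscles()))
  long <- df |>
    tidyr::pivot_longer(c("mean_left", "mean_right"), names_to = "side",
                        values_to = "mean_pct_mvc",
                        names_prefix = "mean_")
  if ("speed" %in% names(df) && any(!is.na(df$speed))) {
    stars <- df |> dplyr::filter(.data$significant) |>
      dplyr::mutate(y = pmax(.data$mean_left, .data$mean_right) * 1.05)
    ggplot2::ggplot(long, ggplot2::aes(.data$speed, .data$mean_pct_mvc,
                                       colour = .data$side)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::geom_text(data = stars,
                         ggplot2::aes(.data$speed, .data$y, label = "*"),
                         inherit.aes = FALSE) +
      ggplot2::facet_wrap(ggplot2::vars(.data$muscle), scales = "free_y") +
      ggplot2::labs(x = "Treadmill speed (km/h)", y = "Mean %MVC",
                    colour = "Side")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$muscle, .data$mean_pct_mvc,
                                       fill = .data$side)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "Mean %MVC", fill = "Side")
  }
}

#' @rdname autoplot.emg_ensemble
#' @export
plot_ensemble <- function(object, ...) autoplot.emg_ensemble(object, ...)

#' @rdname autoplot.asymmetry_report
#' @export
plot_asymmetry <- function(object, ...) autoplot.asymmetry_report(object, ...)
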