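#' Plot a spectrogram
#'
#' Time-frequency heat map with time in days on the x-axis and frequency
#' in Hz on the y-axis; power is displayed on a log10 colour scale (all
#' quantitative work in the package stays on the linear V^2 scale).
#'
#' @param object A `myco_spectrogram`.
#' @param floor_quantile Powers below this quantile are clipped before the
#'   log transform so empty bins do not dominate the colour range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot myco_spectrogram
#' @export
autoplot.myco_spectrogram <- function(object, floor_quantile = 0.01, ...) {
  df <- tidy(object)
  flr <- stats::quantile(df$power[df$power > 0], floor_quantile, na.rm = TRUE)
  df$log_power <- log10(pmax(df$power, flr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 86400, y = .data$freq,
                                   fill = .data$log_power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ power)) +
    ggplot2::labs(x = "Time (days)", y = "Frequency (Hz)") +
    ggplot2::coord_cartesian(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot per-channel band powers of a comparison
#'
#' Dot plot of the per-channel band-integrated powers behind a
#' [compare_conditions()] result, one column per group, log10 y-axis.
#'
#' @param object A `myco_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot myco_comparison
#' @export
autoplot.myco_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = object$group_a$label,
                   power = object$group_a$channel_powers),
    tibble::tibble(group = object$group_b$label,
                   power = object$group_b$channel_powers)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$power)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression(Band ~ power ~ (V^2)),
                  subtitle = sprintf("%s: %+.1f%%, p = %s",
                                     object$label, object$percent_change,
                                     if (is.null(object$welch)) "n/a"
                                     else format.pval(object$welch$p, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Plot a raw voltage trace
#'
#' @param set A `myco_recordings` tibble.
#' @param channels Channel ids to draw (default: all).
#' @param downsample Keep every k-th sample for display (default chosen to
#'   draw at most ~20000 points per channel).
#' @return A ggplot object.
#' @export
plot_traces <- function(set, channels = NULL, downsample = NULL) {
  validate_recording_set(set)
  if (!is.null(channels)) set <- set[set$channel_id %in% channels, ]
  n <- if (nrow(set)) length(set$samples[[1]]) else 0
  if (is.null(downsample)) downsample <- max(1, n %/% 20000)
  fs <- sampling_rate(set)
  df <- purrr::map_dfr(seq_len(nrow(set)), function(i) {
    idx <- seq(1, n, by = downsample)
    tibble::tibble(
      channel_id = set$channel_id[i],
      time = (idx - 1) / fs,
      voltage = set$samples[[i]][idx]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time / 86400,
                                   y = .data$voltage * 1e6)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~channel_id) +
    ggplot2::labs(x = "Time (days)", y = "Voltage (µV)") +
    ggplot2::theme_minimal()
}
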