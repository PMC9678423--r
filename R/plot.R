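band_shading <- function(bands) {
  df <- as_tibble(bands)
  ggplot2::geom_rect(
    data = df,
    ggplot2::aes(xmin = .data$lo_hz, xmax = .data$hi_hz,
                 ymin = -Inf, ymax = Inf, fill = .data$band),
    alpha = 0.12, inherit.aes = FALSE
  )
}

#' Plot a transfer-function analysis
#'
#' Gain, phase and coherence against frequency with the VLF/LF/HF bands
#' shaded.
#'
#' @param object A `tfa_result`.
#' @param bands A [band_scheme()] used for the shading.
#' @param max_freq_hz Right edge of the frequency axis (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfa_result
#' @export
autoplot.tfa_result <- function(object, bands = band_scheme(),
                                max_freq_hz = 0.5, ...) {
  df <- tidy(object)
  df <- df[df$freq_hz > 0 & df$freq_hz <= max_freq_hz, ]
  long <- tidyr::pivot_longer(
    df[, c("freq_hz", "gain_ms_per_mmhg", "phase_rad", "coherence")],
    cols = -"freq_hz", names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("gain_ms_per_mmhg", "phase_rad",
                                     "coherence"),
                          labels = c("gain (ms/mmHg)", "phase (rad)",
                                     "coherence"))
  ggplot2::ggplot(long, ggplot2::aes(.data$freq_hz, .data$value)) +
    band_shading(bands) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, fill = "band",
                  title = "SBP → RR transfer function") +
    ggplot2::theme_minimal()
}

#' Plot a beat series
#'
#' Tachogram (RR) and beat-to-beat systolic pressure; flagged beats are
#' marked.
#'
#' @param object A [beat_series].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beat_series
#' @export
autoplot.beat_series <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("t_s", "rr_ms", "sbp_mmhg", "valid")],
                              cols = c("rr_ms", "sbp_mmhg"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("rr_ms", "sbp_mmhg"),
                         labels = c("RR (ms)", "SBP (mmHg)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$valid), size = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "red")) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, color = "valid") +
    ggplot2::theme_minimal()
}

#' Plot auto-spectra of a spectral estimate
#'
#' @param object A `spectral_estimate`.
#' @param bands A [band_scheme()] used for the shading.
#' @param max_freq_hz Right edge of the frequency axis (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectral_estimate
#' @export
autoplot.spectral_estimate <- function(object, bands = band_scheme(),
                                       max_freq_hz = 0.5, ...) {
  df <- as_tibble(object)[, c("freq_hz", "sxx", "syy")]
  df <- df[df$freq_hz > 0 & df$freq_hz <= max_freq_hz, ]
  long <- tidyr::pivot_longer(df, cols = c("sxx", "syy"),
                              names_to = "channel", values_to = "psd")
  long$channel <- factor(long$channel, levels = c("sxx", "syy"),
                         labels = c("SBP (mmHg²/Hz)", "RR (ms²/Hz)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$freq_hz, .data$psd)) +
    band_shading(bands) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "power spectral density",
                  fill = "band") +
    ggplot2::theme_minimal()
}
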