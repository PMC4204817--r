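#' Heatmap of a detection surface
#'
#' Detection probability as a function of integration window and PSC
#' amplitude (in units of the injected-current SD), facetted by sign and
#' population size — the standard presentation of decoder output.
#'
#' @param surface A [detection_surface()] result (parametric rows are
#'   used if both methods are present).
#' @return A ggplot object.
#' @export
plot_detection_surface <- function(surface) {
  df <- surface[surface$method == surface$method[1], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T_ms, y = .data$amplitude_sd,
                                   fill = .data$detection)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(sign ~ N, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Integration window T (ms)",
                  y = "PSC amplitude (units of current SD)",
                  fill = "Detection\nprobability") +
    ggplot2::theme_minimal()
}

#' Amplitude slices through a detection surface
#'
#' Detection probability versus amplitude at fixed integration windows,
#' overlaying parametric (lines/diamonds) and bootstrap (circles)
#' estimates when both are present.
#'
#' @param surface A [detection_surface()] result.
#' @param T_ms Integration windows to slice at.
#' @param N Population size to show.
#' @return A ggplot object.
#' @export
plot_amplitude_slices <- function(surface, T_ms, N) {
  df <- surface[surface$T_ms %in% T_ms & surface$N == N, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude_sd,
                                   y = .data$detection,
                                   colour = .data$sign,
                                   shape = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = df[df$method == "parametric", ]) +
    ggplot2::facet_wrap(~T_ms, labeller = ggplot2::label_both) +
    ggplot2::scale_shape_manual(values = c(parametric = 18, bootstrap = 1)) +
    ggplot2::labs(x = "PSC amplitude (units of current SD)",
                  y = "Detection probability") +
    ggplot2::theme_minimal()
}

#' Plot an onset-triggered PSTH
#'
#' @param psth A [build_psth()] result.
#' @param groups Optional subset of amplitude groups to show.
#' @return A ggplot object.
#' @export
plot_psth <- function(psth, groups = NULL) {
  if (!is.null(groups)) psth <- psth[psth$group %in% groups, ]
  ggplot2::ggplot(psth, ggplot2::aes(x = .data$t_ms, y = .data$rate_hz,
                                     colour = factor(.data$group))) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~sign) +
    ggplot2::labs(x = "Time from PSC onset (ms)", y = "Firing rate (Hz)",
                  colour = "Amplitude\ngroup") +
    ggplot2::theme_minimal()
}
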