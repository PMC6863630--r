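#' Plot an averaged oEPSC with its detection landmarks
#'
#' Shows the smoothed averaged trace with pulse onsets and, when a
#' measurement table is supplied, the detected peaks.
#'
#' @param object An `oepsc_average` from [average_aligned()].
#' @param measurements Optional per-pulse tibble from
#'   [measure_oepsc_train()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oepsc_average <- function(object, measurements = NULL, ...) {
  p <- ggplot2::ggplot(tidy.opto_sweep(object$smoothed),
                       ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$windows$onset_s,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(measurements)) {
    det <- dplyr::filter(measurements, .data$detected)
    if (nrow(det) > 0) {
      p <- p + ggplot2::geom_point(
        data = tibble::tibble(time_s = det$peak_time_s,
                              value = det$baseline_mean - det$amplitude),
        colour = "firebrick"
      )
    }
  }
  p
}

#' Plot mediolateral bouton-density profiles
#'
#' @param counts ROI-count data frame.
#' @param region Region to profile.
#' @return A ggplot object (one line per animal).
#' @export
plot_ml_profile <- function(counts, region = "GP") {
  prof <- ml_profile(counts, region)
  ggplot2::ggplot(prof, ggplot2::aes(.data$ml_position, .data$density,
                                     colour = .data$animal_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cortical_source) +
    ggplot2::labs(x = "M/L position (mm)",
                  y = "bouton density (/100x100 um^2)",
                  title = region, colour = "animal") +
    ggplot2::theme_minimal()
}

#' Plot connection probabilities per group
#'
#' Bar chart of responder fractions per (cortical source, projection
#' class) with the responder counts printed on the bars.
#'
#' @param x A `connection_analysis` from [connection_table_analysis()].
#' @return A ggplot object.
#' @export
plot_connection_probability <- function(x) {
  stopifnot(inherits(x, "connection_analysis"))
  ggplot2::ggplot(x$counts,
                  ggplot2::aes(.data$projection_class, .data$fraction,
                               fill = .data$cortical_source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%d/%d", .data$n_responsive, .data$n_total)),
      position = ggplot2::position_dodge(width = 0.9), vjust = -0.3, size = 3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction innervated", fill = "source") +
    ggplot2::theme_minimal()
}
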