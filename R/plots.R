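# ggplot2 displays of the main result types.

#' Plot a smoothed CGH profile with calling thresholds
#'
#' @param cgh Long CGH tibble.
#' @param tumor_id Tumor to display.
#' @param thresholds A [threshold_pair()]; drawn as dashed lines.
#' @param window Window width in bp.
#' @return A ggplot object: windowed mean log2 ratio along each chromosome.
#' @export
plot_cgh_profile <- function(cgh, tumor_id, thresholds = threshold_pair(),
                             window = 130000) {
  wins <- sliding_window_mean(cgh, tumor_id, window = window)
  wins <- wins[wins$n_probes > 0, ]
  ggplot2::ggplot(wins, ggplot2::aes(
    x = (.data$win_start + .data$win_end) / 2e6, y = .data$mean_log2
  )) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = thresholds$amp_threshold,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::geom_hline(yintercept = thresholds$del_threshold,
                        linetype = "dashed", color = "navy") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(
      x = "position (Mb)", y = "mean log2(tumor/reference)",
      title = sprintf("CGH profile, %s (%d-kb windows)", tumor_id, window / 1000)
    ) +
    ggplot2::theme_minimal()
}

#' Plot normalized expression window summaries
#'
#' @param windows Output of [chromosome_window_summary()].
#' @return A ggplot object: per-window mean normalized expression ratio.
#' @export
plot_expression_windows <- function(windows) {
  ggplot2::ggplot(
    windows[windows$n_genes > 0, ],
    ggplot2::aes(x = (.data$win_start + .data$win_end) / 2e6,
                 y = .data$mean_ratio)
  ) +
    ggplot2::geom_hline(yintercept = 1, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "mean expression ratio") +
    ggplot2::theme_minimal()
}

#' Plot a driver screen: correlation against its significance threshold
#'
#' @param object A `driver_screen` from [identify_drivers()].
#' @param ... Unused.
#' @return A ggplot object: per-candidate R vs the sample-size-adjusted
#'   critical R, colored by pass/fail.
#' @export
autoplot.driver_screen <- function(object, ...) {
  cc <- object$candidates
  cc <- cc[!is.na(cc$R), ]
  ggplot2::ggplot(cc, ggplot2::aes(
    x = .data$R_crit, y = .data$R, color = .data$passed,
    shape = .data$status
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "critical R (sample-size adjusted)", y = "observed Pearson R",
      color = "passed all filters", shape = "status"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
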