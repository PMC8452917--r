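# Publication-style figures for validation reports.

#' Bland-Altman plot
#'
#' @param ba A [bland_altman()] result.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, xlab = "Mean of methods",
                              ylab = "Difference between methods") {
  df <- ba$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf(
                    "mean difference %.3f, 95%% LoA: %.3f, %.3f",
                    ba$bias, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_classic()
}

#' Scatter plot of simulated against invasive FFR
#'
#' Dashed lines mark the ischemia threshold on both axes.
#'
#' @param paired Data.frame with columns `ffr_invasive`, `ffr_b` and
#'   optionally `phase`.
#' @param threshold Ischemia threshold.
#' @return A ggplot object.
#' @export
plot_ffr_agreement <- function(paired, threshold = 0.80) {
  p <- ggplot2::ggplot(paired,
                       ggplot2::aes(x = .data$ffr_invasive, y = .data$ffr_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Invasive FFR", y = "Simulated FFR") +
    ggplot2::theme_classic()
  if ("phase" %in% names(paired)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$phase), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}
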