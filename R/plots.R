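# ggplot2 displays for the evaluation results.

#' Plot a phase-transition analysis
#'
#' Per-bin fraction of similar binding modes (iRMSD below the cutoff)
#' against the similarity score, with the detected transition point.
#'
#' @param object A [phase_transition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_transition <- function(object, ...) {
  bins <- dplyr::filter(object$bins, .data$n > 0)
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_left + object$bin_width / 2,
                                          y = .data$fraction)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "steelblue") +
    ggplot2::labs(
      x = "3D2D score (bin midpoint)",
      y = sprintf("fraction of pairs with iRMSD <= %g Å", object$irmsd_cut)
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.na(object$transition)) {
    p <- p + ggplot2::geom_vline(xintercept = object$transition,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a top-n success-rate curve
#'
#' @param object A [success_rate()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.success_rate_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$success_rate)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "top n models",
                  y = sprintf("success rate (ligand RMSD <= %g Å)",
                              attr(object, "threshold") %||% 10)) +
    ggplot2::theme_minimal()
}

#' Plot binding-site metric curves over top-n predictions
#'
#' @param metrics A tibble from [topn_metrics()].
#' @return A ggplot object with one line per metric.
#' @export
plot_site_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "n", "sn", "sp", "pre", "acc", "mcc"),
    -"n", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "top n predictions", y = "metric value") +
    ggplot2::theme_minimal()
}
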