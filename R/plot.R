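#' Plot a change-detection result
#'
#' Three aligned panels over the decimated-sample axis: the signal (when
#' supplied), the anomaly scores, and the martingale trajectory on a log
#' scale with the decision threshold; detected change points are drawn as
#' vertical lines in every panel.
#'
#' @param object A `change_detection` object.
#' @param stream Optionally, the [signal_stream()] the detection was run on
#'   (post-decimation), to include the signal panel.
#' @param ... Unused.
#' @return A ggplot (patchwork stack if the `patchwork` package is
#'   available and more than one panel is drawn, otherwise a faceted
#'   ggplot).
#' @method autoplot change_detection
#' @export
autoplot.change_detection <- function(object, stream = NULL, ...) {
  trace <- object$trace
  lambda <- object$config$lambda
  ch <- object$changes$decimated_index

  long <- dplyr::bind_rows(
    if (!is.null(stream)) {
      tibble::tibble(panel = "signal", index = stream$index,
                     value = stream$amplitude)
    },
    tibble::tibble(panel = "anomaly score", index = trace$decimated_index,
                   value = trace$s),
    tibble::tibble(panel = "martingale M(t)", index = trace$decimated_index,
                   value = trace$M)
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))

  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "decimated sample index", y = NULL,
      title = sprintf("%s: %d change(s) at lambda = %g",
                      object$stream_id, length(ch), lambda)
    ) +
    ggplot2::theme_minimal()
  p <- p + ggplot2::geom_hline(
    data = tibble::tibble(panel = factor("martingale M(t)",
                                         levels = levels(long$panel)),
                          y = lambda),
    ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "red"
  )
  if (length(ch) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = ch, colour = "red",
                                 alpha = 0.6, linewidth = 0.3)
  }
  p
}

#' Plot a threshold sweep
#'
#' Precision, recall and F-score as functions of the decision threshold:
#' the precision/recall trade-off that the threshold controls.
#'
#' @param sweep Tibble from [lambda_sweep()].
#' @return A ggplot.
#' @export
plot_lambda_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep[, c("lambda", "precision", "recall", "f_score")],
    cols = -"lambda", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(lambda), y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
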