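#' Plot a performance curve
#'
#' Convenience ggplot of correct rate versus known-set size (log2 axis),
#' one line per task/strategy, with the chance level dashed.
#'
#' @param curve Data frame from [performance_curve()].
#' @param chance Chance level to mark (default 0.5).
#' @return A ggplot object.
#' @export
plot_performance_curve <- function(curve, chance = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_performance_curve() needs the ggplot2 package")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_known, y = .data$rate,
                                      colour = .data$task,
                                      linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "already-known appearances", y = "correct rate") +
    ggplot2::theme_minimal()
}
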