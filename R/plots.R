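# ggplot2 surfaces for the main result types.

#' @method autoplot se_ranking
#' @export
autoplot.se_ranking <- function(object, ...) {
  enh <- object$enhancers
  ggplot2::ggplot(enh, ggplot2::aes(x = .data$rank, y = .data$net_signal,
                                    colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$cutoff_value,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "super-enhancer") +
    ggplot2::labs(x = "enhancer rank (ascending signal)",
                  y = "background-subtracted signal",
                  title = "Rank-ordered enhancer signal")
}

#' @method autoplot maxstat_cut
#' @export
autoplot.maxstat_cut <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutpoint, y = abs(.data$z))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "candidate cutpoint", y = "|standardized log-rank Z|",
                  title = "Maximally selected rank statistic")
}

#' @method autoplot score_split
#' @export
autoplot.score_split <- function(object, ...) {
  km <- object$km |>
    group_by(.data$risk_group) |>
    dplyr::reframe(time = c(0, .data$time),
                   survival = c(1, .data$survival)) |>
    ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$risk_group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(high = "firebrick",
                                            low = "forestgreen")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  title = sprintf("Risk-score split (log-rank p = %.2g)",
                                  object$logrank$p_value))
}

#' Bar plot of peak feature proportions
#'
#' @param annotation Output of [annotate_peaks()].
#' @return A ggplot object.
#' @export
plot_feature_proportions <- function(annotation) {
  props <- feature_proportions(annotation)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$feature,
                                      y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of peaks",
                  title = "Peak distribution over genomic features") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
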