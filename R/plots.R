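# ggplot2 displays for the result types: balance bars, weight diagnostics,
# and the protocol's error summaries.

#' Plot balance before and after instance weighting
#'
#' Grouped bars of the absolute standardized difference of the target across
#' the two confound levels, unweighted versus instance-weighted, one pair per
#' sample — the balance diagnostic that should shrink after weighting.
#'
#' @param object A `balance_report` ([weighted_standardized_difference()]) or
#'   a tibble binding several such rows (one per sample).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.balance_report <- function(object, ...) {
  df <- as_tibble(object)
  df$sample <- factor(seq_len(nrow(df)))
  long <- tidyr::pivot_longer(
    df[, c("sample", "std_diff_unweighted", "std_diff_weighted")],
    cols = -"sample", names_to = "kind", values_to = "std_diff")
  long$kind <- factor(long$kind, c("std_diff_unweighted", "std_diff_weighted"),
                      c("original", "weighted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = abs(.data$std_diff),
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "sample", y = "|standardized difference|", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot instance weights against the target by confound level
#'
#' @param object An [instance_weights][compute_instance_weights] object.
#' @param y,group Optional target values and confound labels to plot
#'   against; with `y` absent, a weight histogram is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.instance_weights <- function(object, y = NULL, group = NULL, ...) {
  df <- as_tibble(object)
  if (is.null(y)) {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$weight)) +
             ggplot2::geom_histogram(bins = 30) +
             ggplot2::labs(x = "instance weight", y = "count") +
             ggplot2::theme_minimal())
  }
  df$y <- y
  df$group <- if (is.null(group)) factor(1) else factor(group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$weight,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "target", y = "instance weight", colour = "confound") +
    ggplot2::theme_minimal()
}

#' Plot protocol error summaries
#'
#' `type = "signed"` draws boxplots of the signed group-difference errors per
#' target subset and strategy (the display that reveals bias-direction
#' shifts); `type = "mse"` draws per-run MSE boxplots per strategy.
#'
#' @param object A [run_protocol()] result.
#' @param type `"signed"` or `"mse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protocol_result <- function(object, type = c("signed", "mse"), ...) {
  type <- match.arg(type)
  m <- object$metrics
  if (type == "mse") {
    return(ggplot2::ggplot(m, ggplot2::aes(x = .data$strategy, y = .data$mse)) +
             ggplot2::geom_boxplot() +
             ggplot2::labs(y = "test MSE") + ggplot2::theme_minimal())
  }
  long <- tidyr::pivot_longer(m, c("signed_diff_low", "signed_diff_high"),
                              names_to = "subset", values_to = "signed")
  long$subset <- factor(long$subset, c("signed_diff_low", "signed_diff_high"),
                        c("low target", "high target"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset, y = .data$signed)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~strategy) +
    ggplot2::labs(y = "signed group-difference MSE") +
    ggplot2::theme_minimal()
}
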