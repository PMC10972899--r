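#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Confusion-matrix heatmap for an evaluation result
#'
#' @param object A `crawl_eval` from [run_protocol()].
#' @param ... Unused.
#' @return A ggplot: true class on the vertical axis, predicted on the
#'   horizontal, tile fill and label giving the pooled counts.
#' @method autoplot crawl_eval
#' @export
autoplot.crawl_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf(
        "%s / %s / %s speed (overall %.2f%%)",
        object$classifier, object$protocol, object$speed, overall_accuracy(object)
      ),
      x = "predicted mode", y = "true mode", fill = "cycles"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D embedding
#'
#' @param embedding Tibble from [embed_2d()].
#' @param colour Column to colour by (default `mode`).
#' @return A ggplot of the embedded cycles.
#' @export
plot_embedding <- function(embedding, colour = "mode") {
  ggplot2::ggplot(
    embedding,
    ggplot2::aes(.data$dim1, .data$dim2, colour = .data[[colour]])
  ) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-speed gait statistics
#'
#' @param gait_summary Tibble from [summarize_gait()].
#' @return A ggplot with one panel per statistic (stance duration, swing
#'   duration, duty factor), mean with sd error bars per speed.
#' @export
plot_gait_summary <- function(gait_summary) {
  long <- gait_summary |>
    tidyr::pivot_longer(
      cols = c("stance_mean", "swing_mean", "duty_mean"),
      names_to = "stat", values_to = "mean"
    ) |>
    dplyr::mutate(
      sd = dplyr::case_when(
        .data$stat == "stance_mean" ~ .data$stance_sd,
        .data$stat == "swing_mean" ~ .data$swing_sd,
        TRUE ~ .data$duty_sd
      ),
      stat = dplyr::recode(.data$stat,
        stance_mean = "stance (s)", swing_mean = "swing (s)",
        duty_mean = "duty factor (%)"
      ),
      speed = factor(.data$speed, levels = c("low", "medium", "fast"))
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$speed, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of self-selected mode proportions per speed
#'
#' @param proportions Tibble from [analyze_self_selected()].
#' @return A ggplot of assigned-mode percentages per speed condition.
#' @export
plot_self_selected <- function(proportions) {
  ggplot2::ggplot(
    proportions,
    ggplot2::aes(.data$mode, .data$pct, fill = .data$speed)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "assigned mode", y = "proportion of cycles (%)") +
    ggplot2::theme_minimal()
}
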