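# ggplot2 diagnostics.

#' Barcode rank curve plot
#'
#' Log-log plot of molecule count vs. barcode rank, with optional size
#' thresholds drawn as horizontal lines.
#'
#' @param sizes Per-barcode molecule counts.
#' @param thresholds Optional output of [size_thresholds()].
#' @return A ggplot object.
#' @export
plot_rank_curve <- function(sizes, thresholds = NULL) {
  rc <- rank_curves(sizes)$rank_curve
  p <- ggplot2::ggplot(rc, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "molecules") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(thresholds$t_l, thresholds$t_u),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' UMI frequency distribution plot
#'
#' Occurrence frequencies of UMI sequences ordered by rank, highlighting
#' the skew of the pool.
#'
#' @param dist An `umi_distribution`.
#' @return A ggplot object.
#' @export
plot_umi_distribution <- function(dist) {
  df <- tibble(
    rank = seq_along(dist$probs),
    probability = sort(dist$probs, decreasing = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "UMI rank", y = "probability") +
    ggplot2::theme_minimal()
}

#' Edit-distance profile comparison plot
#'
#' @param comparison Output of [edit_distance_relative_difference()].
#' @return A ggplot object.
#' @export
plot_edit_distance <- function(comparison) {
  df <- tidyr::pivot_longer(
    comparison %>% select("distance", "observed", "theoretical"),
    -"distance", names_to = "which", values_to = "probability"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$probability,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Hamming distance", y = "probability") +
    ggplot2::theme_minimal()
}

#' Cell quality score plot
#'
#' Scores against cell size, coloured by filtering status.
#'
#' @param cell_table Per-cell table from [run_pipeline()] / [filter_cells()].
#' @return A ggplot object.
#' @export
plot_cell_quality <- function(cell_table) {
  ggplot2::ggplot(cell_table, ggplot2::aes(x = .data$size, y = .data$score,
                                           colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "molecules", y = "quality score") +
    ggplot2::theme_minimal()
}
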