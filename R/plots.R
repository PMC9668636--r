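#' Plot a group-level connectivity matrix
#'
#' Heatmap of a probability or group-FA matrix; zero entries (no connection)
#' are drawn as background.
#'
#' @param m group-level matrix.
#' @param title optional title.
#' @return A ggplot object.
#' @export
plot_probability_matrix <- function(m, title = NULL) {
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  df$value[df$value == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "black", name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "node", y = "node", title = title) +
    ggplot2::theme_minimal()
}

#' Effect-size histogram of edgewise results
#'
#' Histogram of Cohen's d over tested edges, with the large-effect gate
#' marked.
#'
#' @param object an `edge_test_result`.
#' @param d_threshold gate to mark (default 0.8).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.edge_test_result <- function(object, d_threshold = 0.8, ...) {
  df <- object[object$testable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = d_threshold, colour = "red", linetype = 2) +
    ggplot2::labs(
      x = "Cohen's d (controls - patients)", y = "connections",
      title = sprintf("k = %d connections tested", sum(object$testable))
    ) +
    ggplot2::theme_minimal()
}

#' Cross-site consistency by analysis condition
#'
#' Mean relative difference (%) between site pairs for probability and FA
#' group matrices, under no processing, harmonization only, thresholding
#' only, and both.
#'
#' @param object an `svd_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.svd_experiment <- function(object, ...) {
  df <- object$consistency
  df$condition <- factor(df$condition, c("none", "harmonized", "thresholded", "both"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$mean_pct, fill = .data$metric
  )) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "cross-site relative difference (%)",
      fill = "group matrix"
    ) +
    ggplot2::theme_minimal()
}
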