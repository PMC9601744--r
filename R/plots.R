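#' Score-drop (elbow) plot of a ranked item table
#'
#' Plots the composite score against rank, coloured by cluster when clusters
#' have been assigned, with the percentage drop annotated between successive
#' items — the visual counterpart of the >30%-drop clustering rule.
#'
#' @param object A `cog_rank_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cog_rank_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  has_cluster <- "cluster" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$avg_score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_text(
      data = df[!is.na(df$drop_pct), ],
      ggplot2::aes(label = sprintf("%.1f%%", .data$drop_pct)),
      vjust = -1.1, size = 3, colour = "grey30"
    )
  p <- if (has_cluster) {
    p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$cluster)),
      size = 2.5
    ) +
      ggplot2::labs(colour = "Cluster")
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
  p +
    ggplot2::scale_x_continuous(
      breaks = df$rank, labels = df$item,
      guide = ggplot2::guide_axis(angle = 45)
    ) +
    ggplot2::labs(
      x = NULL, y = "Composite normalized score",
      title = "Item ranking and score drops"
    ) +
    ggplot2::theme_minimal()
}

#' Metric plot of cross-validation results
#'
#' Bar chart of accuracy, sensitivity and specificity per classifier,
#' faceted by subset and demographic phase when those columns are present.
#'
#' @param object A `cog_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cog_eval <- function(object, ...) {
  long <- tidy.cog_eval(object)
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$classifier, y = .data$value, fill = .data$metric)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "Percent", fill = NULL,
      title = "Cross-validated classification performance"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (all(c("subset", "phase") %in% names(long))) {
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$subset),
      cols = ggplot2::vars(.data$phase)
    )
  }
  p
}

#' Heatmap of an item correlation matrix
#'
#' @param cor_mat A correlation matrix from [pearson_matrix()].
#' @return A ggplot tile plot of the pairwise Pearson coefficients.
#' @export
plot_correlation <- function(cor_mat) {
  df <- tibble::as_tibble(as.data.frame(as.table(cor_mat)),
    .name_repair = ~ c("item_a", "item_b", "r")
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$item_a, y = .data$item_b, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
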