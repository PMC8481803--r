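# ggplot2 visualizations for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot top enrichment results
#'
#' Horizontal bars of `-log10(p_adj)` for the strongest categories,
#' colored by direction.
#'
#' @param object A `tk_enrichment` tibble.
#' @param n_top Number of categories shown (default 10).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tk_enrichment <- function(object, n_top = 10, ...) {
  df <- utils::head(dplyr::arrange(
    tibble::as_tibble(object), .data$p_adj, .data$p_raw
  ), n_top)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adj), y = .data$category, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      enriched = "#c0392b", depleted = "#27ae60", none = "grey60"
    )) +
    ggplot2::labs(
      x = expression(-log[10] ~ "adjusted p"), y = NULL,
      fill = "direction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the running-sum statistic for one category
#'
#' Draws the running sum over the ranked list with a rug marking member
#' gene positions, the standard diagnostic view of a running-sum
#' enrichment result.
#'
#' @param ranked A tibble `gene`, `score`.
#' @param category Character vector of category members.
#' @param weight_p Score-weighting exponent passed to [gsea_es()].
#' @return A ggplot object.
#' @export
plot_running_sum <- function(ranked, category, weight_p = 1) {
  res <- gsea_es(ranked, category, weight_p = weight_p)
  df <- tibble::tibble(
    rank = seq_along(res$running_sum), running_sum = res$running_sum
  )
  hits <- tibble::tibble(rank = res$hit_positions)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_line(color = "#c0392b") +
    ggplot2::geom_rug(
      data = hits, ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
      sides = "b", length = ggplot2::unit(0.04, "npc")
    ) +
    ggplot2::labs(
      x = "rank in sorted gene list", y = "running sum",
      subtitle = paste0("ES = ", format(res$es, digits = 4))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cell activity by group
#'
#' Violin + jitter of one category's per-cell activity scores
#' (`-log10 p`) across cell groups.
#'
#' @param object A `tk_cell_activity` object.
#' @param category Category name (default: first column).
#' @param group_key Grouping column of the cell metadata.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tk_cell_activity <- function(object, category = NULL,
                                      group_key = "group", ...) {
  category <- category %||% colnames(object$activity)[1]
  df <- tibble::tibble(
    activity = object$activity[, category],
    group = as.character(object$cell_data[[group_key]])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$activity)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::labs(
      y = expression(-log[10] ~ "p"), x = NULL, subtitle = category
    ) +
    ggplot2::theme_minimal()
}

#' Plot time-course cluster centroids
#'
#' One panel per cluster showing member courses (grey) and the centroid
#' (red).
#'
#' @param object A `tk_clusters` object.
#' @param tc The `tk_timecourse` the clustering was computed on.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tk_clusters <- function(object, tc = NULL, ...) {
  cent <- tibble::as_tibble(object$centroids, rownames = "cluster")
  cent <- tidyr::pivot_longer(cent, -"cluster",
    names_to = "time", values_to = "value"
  )
  cent$time <- as.numeric(cent$time)
  p <- ggplot2::ggplot(
    cent, ggplot2::aes(.data$time, .data$value, group = .data$cluster)
  )
  if (!is.null(tc)) {
    mem <- tibble::as_tibble(tc$values, rownames = "gene")
    mem <- tidyr::pivot_longer(mem, -"gene",
      names_to = "time", values_to = "value"
    )
    mem$time <- as.numeric(mem$time)
    mem <- dplyr::left_join(mem, object$assignment, by = "gene")
    mem$cluster <- paste0("cluster_", mem$cluster)
    p <- p + ggplot2::geom_line(
      data = mem,
      ggplot2::aes(group = .data$gene),
      color = "grey75", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_line(color = "#c0392b", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time", y = "expression") +
    ggplot2::theme_minimal()
}

#' Plot regulator prioritization results
#'
#' Dot plot of the top regulators by adjusted p, colored by mean
#' regulator-target correlation (red positive, blue negative).
#'
#' @param object A `tk_regulators` tibble.
#' @param n_top Number of regulators shown (default 15).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tk_regulators <- function(object, n_top = 15, ...) {
  df <- utils::head(
    dplyr::arrange(tibble::as_tibble(object), .data$p_adj, .data$p_raw),
    n_top
  )
  df$regulator <- factor(df$regulator, levels = rev(df$regulator))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adj), y = .data$regulator,
    color = .data$mean_correlation, size = .data$n_targets_in_list
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(
      low = "#2980b9", mid = "grey80", high = "#c0392b", midpoint = 0,
      limits = c(-1, 1)
    ) +
    ggplot2::labs(
      x = expression(-log[10] ~ "adjusted p"), y = NULL,
      color = "mean r", size = "targets in list"
    ) +
    ggplot2::theme_minimal()
}
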