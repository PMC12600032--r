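# ggplot2 displays for the main result types.

#' Plot the pc_distance curve with the selected elbow
#'
#' @param object A `k_selection` object from [select_k_elbow()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$pc_curve, ggplot2::aes(x = .data$k, y = .data$pc_distance)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "number of clusters k",
      y = "between-cluster share of total dissimilarity",
      title = sprintf("Elbow selection: k = %d", object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of the cluster-interaction matrix
#'
#' @param object A `cluster_interaction` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_interaction <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$to, y = .data$from,
                                     fill = .data$lambda)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$lambda)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1), name = "lambda") +
    ggplot2::labs(x = "contributes to cluster j'", y = "assemblage of cluster j",
                  title = "Cluster interactions (diagonal = specificity)") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of the cross-validated classifier
#'
#' @param object An `ecosystem_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecosystem_fit <- function(object, ...) {
  long <- as_tibble(object$confusion_pct, rownames = "truth") |>
    tidyr::pivot_longer(-"truth", names_to = "predicted", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "% of class") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "predicted", y = "observed",
      title = sprintf("Confusion (row %%), F1 = %.2f, macro F1 = %.2f",
                      object$f1, object$macro_f1)
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of permutation importance with significance
#'
#' @param object An `ecosystem_importance` tibble.
#' @param alpha Significance level used to mark variables (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecosystem_importance <- function(object, alpha = 0.05, ...) {
  overall <- dplyr::filter(object, .data$class == "overall",
                           .data$metric == "mean_decrease_accuracy") |>
    dplyr::mutate(significant = .data$p_value < alpha)
  ggplot2::ggplot(overall, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$variable, .data$importance),
    colour = .data$significant
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                                 name = sprintf("p < %.2f", alpha)) +
    ggplot2::labs(x = "mean decrease in accuracy", y = NULL,
                  title = "Permutation importance (overall)") +
    ggplot2::theme_minimal()
}

#' Partial-dependence curves per class
#'
#' @param object An `ecosystem_pdp` tibble from [partial_dependence()].
#' @param scale `"log_odds"` (default) or `"prob"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecosystem_pdp <- function(object, scale = c("log_odds", "prob"), ...) {
  scale <- match.arg(scale)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data[[scale]],
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = unique(object$variable),
      y = if (scale == "log_odds") "mean log-odds" else "mean probability",
      title = "Partial dependence"
    ) +
    ggplot2::theme_minimal()
}

#' Draw the cluster-interaction network in environmental space
#'
#' Nodes at per-cluster environmental medians (from [project_network()]),
#' sized by specificity; directed edges for interactions above `min_edge`.
#'
#' @param x A `cluster_interaction` object.
#' @param coords Node coordinates from [project_network()].
#' @param min_edge Minimum off-diagonal interaction to draw (default 0.05).
#' @return A ggplot.
#' @export
plot_network <- function(x, coords, min_edge = 0.05) {
  net <- network_edges(x, min_edge = min_edge)
  nodes <- dplyr::inner_join(coords, net$specificity, by = "cluster")
  edges <- net$edges |>
    dplyr::inner_join(dplyr::rename(coords, x0 = "x", y0 = "y"),
                      by = c("from" = "cluster")) |>
    dplyr::inner_join(dplyr::rename(coords, x1 = "x", y1 = "y"),
                      by = c("to" = "cluster"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$weight),
      colour = "grey50", alpha = 0.7,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$specificity), colour = "darkgreen") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster), vjust = -1.2) +
    ggplot2::scale_size(range = c(2, 8), limits = c(0, 1)) +
    ggplot2::labs(x = attr(coords, "x_var") %||% "x",
                  y = attr(coords, "y_var") %||% "y",
                  title = "Cluster-interaction network") +
    ggplot2::theme_minimal()
}
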