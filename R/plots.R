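#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatterplot of a pairwise mixture fit
#'
#' Points coloured by hard component assignment, with component means
#' marked — the per-pair view of mode discovery.
#'
#' @param object A `gmm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gmm_fit <- function(object, ...) {
  pts <- tibble::tibble(
    x = object$points[, 1], y = object$points[, 2],
    component = factor(object$labels)
  )
  centers <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = centers,
                        ggplot2::aes(x = .data$mean_x, y = .data$mean_y),
                        colour = "black", shape = 4, size = 3,
                        inherit.aes = FALSE) +
    ggplot2::labs(x = "gene A (log2 expression)",
                  y = "gene B (log2 expression)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' RMT scan trajectory plot
#'
#' Chi-square of the NNSD-vs-Poisson test against the candidate threshold,
#' with the acceptance cutoff and (when found) the chosen threshold marked.
#'
#' @param object An `rmt_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmt_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$scan,
                       ggplot2::aes(x = .data$tau, y = .data$chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$chi2_crit, linetype = "dashed") +
    ggplot2::labs(x = "candidate threshold",
                  y = "chi-square (NNSD vs Poisson)") +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_tau)) {
    p <- p + ggplot2::geom_vline(xintercept = object$chosen_tau,
                                 colour = "red", linetype = "dotted")
  }
  p
}

#' Sample-composition heatmap of a network
#'
#' The condition-specific-edge view: samples as rows (optionally grouped by
#' a condition annotation), edges as columns ordered by sample-composition
#' similarity ([order_edges()]); a filled cell means the sample supported
#' the edge (digit `1`).
#'
#' @param object A `conet`.
#' @param groups Optional tibble `sample_id`, `condition` to group rows.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conet <- function(object, groups = NULL, ...) {
  mat <- binarize_sample_strings(object)
  ord <- order_edges(mat)
  sample_ids <- attr(object, "sample_ids")
  row_order <- seq_along(sample_ids)
  if (!is.null(groups)) {
    row_order <- order(groups$condition[match(sample_ids, groups$sample_id)])
  }
  df <- tidyr::expand_grid(edge = seq_len(nrow(mat)),
                           sample = seq_along(sample_ids)) |>
    dplyr::mutate(present = mat[cbind(.data$edge, .data$sample)],
                  edge_pos = match(.data$edge, ord),
                  sample_pos = match(.data$sample, row_order))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$edge_pos,
                                        y = .data$sample_pos,
                                        fill = factor(.data$present))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "firebrick", `1` = "forestgreen"),
                               name = "in cluster") +
    ggplot2::labs(x = "edges (ordered by sample composition)", y = "samples") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  if (!is.null(groups)) {
    cond <- groups$condition[match(sample_ids[row_order], groups$sample_id)]
    breaks <- cumsum(table(cond)[unique(cond)])
    p <- p + ggplot2::geom_hline(yintercept = utils::head(breaks, -1) + 0.5,
                                 colour = "black")
  }
  p
}

#' Degree-distribution plot (log-log)
#'
#' @param network A `conet`.
#' @return A ggplot of node count against degree on log scales; a roughly
#'   linear trend is the usual scale-free diagnostic.
#' @export
plot_degree_distribution <- function(network) {
  ggplot2::ggplot(degree_distribution(network),
                  ggplot2::aes(x = .data$degree, y = .data$n_nodes)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "number of nodes") +
    ggplot2::theme_minimal()
}

#' Clustering-coefficient profile plot (log-log)
#'
#' @param network A `conet`.
#' @return A ggplot of mean local clustering coefficient against degree; a
#'   decreasing trend is the usual hierarchical-structure diagnostic.
#' @export
plot_clustering_profile <- function(network) {
  df <- clustering_coefficient_profile(network) |>
    dplyr::filter(.data$mean_clustering > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = .data$mean_clustering)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "mean clustering coefficient") +
    ggplot2::theme_minimal()
}
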