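# ggplot2 visualisations of matrices, embeddings and reports.

#' Heatmap of a pairwise score matrix
#'
#' @param object A [pepsim_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pepsim_matrix <- function(object, ...) {
  df <- tidy.pepsim_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "orientation")) +
    ggplot2::labs(title = paste("Component:", attr(object, "component")),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a pipeline report
#'
#' `type = "embedding"` draws the NMDS scatter coloured by cluster (shape
#' by true label when present); `type = "knn"` draws per-k sensitivity and
#' specificity curves.
#'
#' @param object A `pepsim_report`.
#' @param type `"embedding"` or `"knn"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pepsim_report <- function(object, type = c("embedding", "knn"),
                                   ...) {
  type <- match.arg(type)
  if (type == "embedding") {
    df <- tidy.pepsim_report(object)
    if (is.null(object$embedding)) stop("report has no embedding")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = factor(.data$cluster)))
    if ("label" %in% names(df)) {
      p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$label),
                                   size = 2.5)
    } else {
      p <- p + ggplot2::geom_point(size = 2.5)
    }
    p + ggplot2::labs(colour = "cluster", shape = "cross-reactive",
                      x = "NMDS1", y = "NMDS2") +
      ggplot2::theme_minimal()
  } else {
    if (is.null(object$knn)) stop("report has no KNN results")
    df <- tidyr::pivot_longer(object$knn, c("sensitivity", "specificity"),
                              names_to = "metric")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_continuous(breaks = unique(df$k)) +
      ggplot2::labs(y = "proportion") +
      ggplot2::theme_minimal()
  }
}

#' Dendrogram plot of the report's clustering
#'
#' @param report A `pepsim_report`.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot_dendrogram <- function(report, ...) {
  ape::plot.phylo(ape::as.phylo(report$hclust), ...)
  invisible(report)
}
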