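#' Plot a haplotype network
#'
#' Draws nodes sized by individual count at a force-directed layout, with
#' alternative links dashed. The layout is deterministic for a given
#' network (fixed seed).
#'
#' @param object A `hap_network`.
#' @param label Draw node labels?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_network <- function(object, label = TRUE, ...) {
  validate_hap_network(object)
  nodes <- object$nodes
  edges <- object$edges
  if (requireNamespace("igraph", quietly = TRUE) && nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to")], directed = FALSE, vertices = nodes$node
    )
    coords <- withr::with_seed(
      42L, igraph::layout_with_fr(g, weights = pmax(edges$weight, 1))
    )
  } else {
    theta <- 2 * pi * (seq_len(nrow(nodes)) - 1) / max(nrow(nodes), 1)
    coords <- cbind(cos(theta), sin(theta))
  }
  layout <- tibble(node = nodes$node, x = coords[, 1], y = coords[, 2],
                   count = nodes$count)
  seg <- dplyr::left_join(edges, layout[, c("node", "x", "y")],
                          by = c(from = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(layout[, c("node", "x", "y")], by = c(to = "node"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, linetype = .data$alternative),
      color = "grey40"
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$count),
      color = "steelblue", alpha = 0.85
    ) +
    ggplot2::scale_linetype_manual(
      values = c(`FALSE` = "solid", `TRUE` = "dashed"),
      guide = "none"
    ) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "Individuals")
  if (label) {
    p <- p + ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 3
    )
  }
  p
}

#' Plot the metrics of a complexity report
#'
#' Bar chart of the diversity/complexity metrics in `[0, 1]` (Hd, Bd, HBd,
#' Nd, HNd), annotated with their 2-decimal values.
#'
#' @param object A `hap_complexity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_complexity <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$metric != "pi") |>
    dplyr::mutate(metric = factor(.data$metric,
                                  levels = c("Hd", "Bd", "HBd", "Nd", "HNd")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rounded)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = object$metrics$dataset) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype-class decomposition
#'
#' Individuals per haplotype class, labeled by branch count.
#'
#' @param object A `hap_classes` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_classes <- function(object, ...) {
  validate_hap_classes(object)
  d <- dplyr::mutate(object,
                     class = paste0(.data$n_branches, "-branch"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class,
                                  y = .data$n_individuals)) +
    ggplot2::geom_col(fill = "darkseagreen4", width = 0.7) +
    ggplot2::labs(x = "Haplotype class", y = "Individuals") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
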