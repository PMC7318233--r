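#' Plot a symptom network
#'
#' Force-directed (Fruchterman–Reingold) drawing: edge width proportional
#' to absolute weight, solid for positive and dashed for negative partial
#' correlations; nodes optionally colored by a community partition.
#'
#' @param object A `symptom_network`.
#' @param partition Optional `community_partition` for node coloring.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symptom_network <- function(object, partition = NULL, seed = 1,
                                     ...) {
  layout <- fruchterman_reingold(object, seed = seed)
  edges <- tidy(object) |>
    dplyr::left_join(layout, by = c(item_i = "item")) |>
    dplyr::left_join(layout, by = c(item_j = "item"),
                     suffix = c("", "_end"))
  nodes <- layout
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, tidy(partition), by = "item")
    nodes$community <- factor(nodes$community)
  }
  gg <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_end,
                   yend = .data$y_end, linewidth = abs(.data$weight),
                   linetype = .data$weight < 0),
      color = "grey40", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 2))
  if (is.null(partition)) {
    gg <- gg + ggplot2::geom_point(data = nodes,
                                   ggplot2::aes(.data$x, .data$y),
                                   size = 10, color = "steelblue")
  } else {
    gg <- gg + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, color = .data$community), size = 10)
  }
  gg +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$item),
                       size = 3) +
    ggplot2::theme_void()
}

#' Plot standardized centrality profiles
#'
#' z-scores of strength, closeness and betweenness per item, one panel per
#' index — the conventional centrality profile figure.
#'
#' @param object A `centrality_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_table <- function(object, ...) {
  long <- tidy(object)
  long$item <- factor(long$item, levels = rev(sort(unique(long$item))))
  ggplot2::ggplot(long, ggplot2::aes(.data$z, .data$item, group = 1)) +
    ggplot2::geom_path(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, nrow = 1) +
    ggplot2::labs(x = "z-score", y = NULL)
}

#' Plot case-dropping stability curves
#'
#' Mean subsample-vs-original centrality correlation per drop proportion
#' with a 2.5–97.5% replicate band and the 0.7 stability threshold.
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_report <- function(object, ...) {
  summ <- object$table |>
    dplyr::group_by(.data$prop, .data$index) |>
    dplyr::summarise(
      mid = mean(.data$correlation, na.rm = TRUE),
      lo = quantile(.data$correlation, 0.025, na.rm = TRUE, names = FALSE),
      hi = quantile(.data$correlation, 0.975, na.rm = TRUE, names = FALSE),
      .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(.data$prop, .data$mid, color = .data$index,
                               fill = .data$index)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$params$cor_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with original centralities")
}
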