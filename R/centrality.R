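#' Node strength centrality
#'
#' Sum of the absolute weights of all edges incident to each node (set
#' `signed = TRUE` for the signed sum, the "expected influence" variant).
#'
#' @param model A `symptom_network` or symmetric weights matrix.
#' @param signed Use signed instead of absolute weights (default FALSE).
#' @return Named numeric vector.
#' @export
strength_centrality <- function(model, signed = FALSE) {
  w <- as_weights(model)
  if (signed) rowSums(w) else rowSums(abs(w))
}

network_distances <- function(w, edge_tol = 1e-10) {
  a <- abs(w)
  a[a <= edge_tol] <- 0
  d <- ifelse(a > 0, 1 / a, 0)   # igraph treats 0-weight entries as absent
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  list(graph = g,
       dist = igraph::distances(g, weights = igraph::E(g)$weight))
}

#' Closeness centrality on inverse-weight distances
#'
#' Edge length is the inverse absolute weight; closeness of a node is the
#' reciprocal of the summed shortest-path distances to its reachable nodes,
#' scaled by the fraction of nodes reached (`reachable / (p - 1)`) so
#' disconnection is penalized. Isolated nodes get 0.
#'
#' @inheritParams strength_centrality
#' @param edge_tol Absolute weight below which an edge is absent.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(model, edge_tol = 1e-10) {
  w <- as_weights(model)
  p <- ncol(w)
  D <- network_distances(w, edge_tol)$dist
  out <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) return(0)
    (sum(reach) / (p - 1)) / sum(d[reach])
  }, numeric(1))
  setNames(out, colnames(w))
}

#' Betweenness centrality on inverse-weight distances
#'
#' Number of shortest paths (edge length = inverse absolute weight) passing
#' through each node, with fractional credit split over tied shortest
#' paths; path endpoints are not counted.
#'
#' @inheritParams closeness_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(model, edge_tol = 1e-10) {
  w <- as_weights(model)
  g <- network_distances(w, edge_tol)$graph
  b <- igraph::betweenness(g, weights = igraph::E(g)$weight, directed = FALSE)
  setNames(as.numeric(b), colnames(w))
}

zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

dense_rank_desc <- function(x) {
  dplyr::dense_rank(dplyr::desc(x))
}

#' Centrality table of a symptom network
#'
#' Node strength, closeness and betweenness (see the per-index functions),
#' each raw, z-standardized, and dense-ranked (rank 1 = most central, ties
#' share a rank).
#'
#' @inheritParams closeness_centrality
#' @param signed Use signed strength (expected influence) instead of
#'   absolute strength.
#' @return A tibble of class `centrality_table`: `item`, `strength`,
#'   `closeness`, `betweenness`, their `_z` and `_rank` columns.
#' @export
#' @examples
#' x <- simulate_cohort(reap_cohort_spec(), seed = 5)
#' centrality(symptom_network(x))
centrality <- function(model, signed = FALSE, edge_tol = 1e-10) {
  w <- as_weights(model)
  if (inherits(model, "symptom_network")) edge_tol <- model$edge_tol
  out <- tibble::tibble(
    item = colnames(w),
    strength = unname(strength_centrality(w, signed = signed)),
    closeness = unname(closeness_centrality(w, edge_tol = edge_tol)),
    betweenness = unname(betweenness_centrality(w, edge_tol = edge_tol))
  )
  for (idx in c("strength", "closeness", "betweenness")) {
    out[[paste0(idx, "_z")]] <- zscore(out[[idx]])
    out[[paste0(idx, "_rank")]] <- dense_rank_desc(out[[idx]])
  }
  class(out) <- c("centrality_table", class(out))
  out
}

#' Top central nodes per index
#'
#' The `k` most central nodes for each index, ordered by descending raw
#' value with lexicographic tie-break on the item code (boundary ties are
#' reported via a message).
#'
#' @param table A `centrality_table` from [centrality()].
#' @param k Number of nodes per index (default 3).
#' @return A tibble `index`, `rank`, `item`, `value`.
#' @export
summarize_top3 <- function(table, k = 3) {
  stopifnot(inherits(table, "centrality_table"), nrow(table) >= k)
  purrr::map_dfr(c("strength", "closeness", "betweenness"), function(idx) {
    ord <- dplyr::arrange(tibble::tibble(item = table$item,
                                         value = table[[idx]]),
                          dplyr::desc(.data$value), .data$item)
    if (nrow(ord) > k && ord$value[k] == ord$value[k + 1]) {
      inform(paste0("tie at rank ", k, " for ", idx,
                    "; lexicographic tie-break applied"))
    }
    tibble::tibble(index = idx, rank = seq_len(k),
                   item = ord$item[seq_len(k)], value = ord$value[seq_len(k)])
  })
}
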