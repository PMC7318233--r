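#' Tidy a tetrachoric estimate into a long pair table
#'
#' @param x A `tetrachoric_estimate`.
#' @param ... Unused.
#' @return A tibble `item_i`, `item_j`, `rho` (one row per unordered pair).
#' @export
tidy.tetrachoric_estimate <- function(x, ...) {
  network_edge_list(x$rho, all = TRUE) |>
    dplyr::rename(rho = "weight")
}

#' @rdname tidy.tetrachoric_estimate
#' @export
glance.tetrachoric_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, p = length(x$items),
                 psd_repaired = x$psd_repaired,
                 min_eigenvalue = x$min_eigenvalue,
                 n_degenerate = x$n_degenerate)
}

#' Tidy a symptom network into an edge list
#'
#' @param x A `symptom_network`.
#' @param all Include zero edges (default `FALSE`).
#' @param ... Unused.
#' @return A tibble `item_i`, `item_j`, `weight`.
#' @export
tidy.symptom_network <- function(x, all = FALSE, ...) {
  network_edge_list(x$weights, edge_tol = x$edge_tol, all = all)
}

#' @rdname tidy.symptom_network
#' @export
glance.symptom_network <- function(x, ...) {
  ce <- count_edges(x)
  tibble::tibble(lambda = x$lambda, ebic = x$ebic, gamma = x$gamma,
                 n = x$n, p = x$p, nonzero = ce$nonzero,
                 possible = ce$possible, percent = ce$percent)
}

#' Tidy a community partition
#'
#' @param x A `community_partition`.
#' @param ... Unused.
#' @return A tibble `item`, `community`, and `isolated` when annotated.
#' @export
tidy.community_partition <- function(x, ...) {
  out <- tibble::tibble(item = names(x$membership),
                        community = unname(x$membership))
  if (!is.null(x$isolated)) out$isolated <- unname(x$isolated)
  out
}

#' @rdname tidy.community_partition
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities,
                 hamiltonian = x$hamiltonian,
                 seed = x$seed %||% NA_integer_)
}

#' Tidy a centrality table into long format
#'
#' @param x A `centrality_table`.
#' @param ... Unused.
#' @return A tibble `item`, `index`, `value`, `z`, `rank`.
#' @export
tidy.centrality_table <- function(x, ...) {
  purrr::map_dfr(c("strength", "closeness", "betweenness"), function(idx) {
    tibble::tibble(item = x$item, index = idx, value = x[[idx]],
                   z = x[[paste0(idx, "_z")]],
                   rank = x[[paste0(idx, "_rank")]])
  })
}

#' Tidy a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return The per-index CS-coefficient tibble.
#' @export
tidy.stability_report <- function(x, ...) x$cs

#' @rdname tidy.stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, seed = x$seed, n_skipped = x$n_skipped,
                 cor_method = x$cor_method,
                 max_proportion = max(x$params$drop_proportions))
}

#' Tidy a bootstrap difference test
#'
#' @param x A `difference_test`.
#' @param ... Unused.
#' @return The pairwise-difference tibble with CIs and significance flags.
#' @export
tidy.difference_test <- function(x, ...) x$differences

#' @rdname tidy.difference_test
#' @export
glance.difference_test <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_skipped = x$n_skipped,
                 conf = x$conf,
                 n_significant = sum(x$differences$significant),
                 n_pairs = nrow(x$differences))
}
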