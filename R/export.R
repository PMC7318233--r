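#' Export a network to standard formats
#'
#' Writes any combination of a long-format edge list (TSV: `item_i`,
#' `item_j`, `weight`), the full weight matrix (CSV with row names), and a
#' weighted undirected GraphML file.
#'
#' @param model A `symptom_network`.
#' @param edgelist,matrix,graphml Optional output paths.
#' @return Invisibly, the vector of paths written.
#' @export
write_network <- function(model, edgelist = NULL, matrix = NULL,
                          graphml = NULL) {
  stopifnot(inherits(model, "symptom_network"))
  written <- character()
  if (!is.null(edgelist)) {
    readr::write_tsv(tidy(model), edgelist)
    written <- c(written, edgelist)
  }
  if (!is.null(matrix)) {
    m <- tibble::as_tibble(model$weights, rownames = "item")
    readr::write_csv(m, matrix)
    written <- c(written, matrix)
  }
  if (!is.null(graphml)) {
    w <- model$weights
    a <- abs(w) > model$edge_tol
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(a, w, 0), mode = "undirected", weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}

#' Export a community partition as JSON
#'
#' @param partition A `community_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  out <- list(membership = as.list(partition$membership),
              n_communities = partition$n_communities,
              hamiltonian = partition$hamiltonian,
              isolated = if (!is.null(partition$isolated))
                as.list(partition$isolated),
              params = partition$params, seed = partition$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export a stability report
#'
#' @param report A `stability_report`.
#' @param json Path for the CS summary (JSON).
#' @param table Optional path for the full replicate correlation table
#'   (CSV, one row per replicate).
#' @return Invisibly, the paths written.
#' @export
write_stability <- function(report, json, table = NULL) {
  stopifnot(inherits(report, "stability_report"))
  out <- list(cs = report$cs, n_boot = report$n_boot, seed = report$seed,
              n_skipped = report$n_skipped, cor_method = report$cor_method,
              params = report$params)
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- json
  if (!is.null(table)) {
    readr::write_csv(report$table, table)
    written <- c(written, table)
  }
  invisible(written)
}

#' Export a prevalence table
#'
#' @param table A prevalence tibble from [prevalence()].
#' @param csv,json Optional output paths.
#' @return Invisibly, the paths written.
#' @export
write_prevalence <- function(table, csv = NULL, json = NULL) {
  written <- character()
  if (!is.null(csv)) {
    readr::write_csv(table, csv)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(table, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json)
  }
  invisible(written)
}
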