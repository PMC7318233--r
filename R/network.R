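#' Graphical lasso at a fixed penalty
#'
#' L1-penalized Gaussian maximum-likelihood estimation of a sparse
#' precision matrix (penalty on off-diagonal entries only), by block
#' coordinate descent. Small entries are set exactly to zero by the
#' soft-threshold update.
#'
#' @param S Positive-definite correlation (or covariance) matrix.
#' @param lambda Nonnegative penalty.
#' @param tol Convergence tolerance on the maximum parameter change
#'   (default `1e-6`).
#' @param maxit Maximum number of outer sweeps.
#' @param warm Optional warm start: list with `covariance` and `beta` from
#'   a previous fit (used internally along the penalty path).
#' @return A list: `precision`, `covariance`, `beta`, `iterations`,
#'   `converged`.
#' @export
#' @examples
#' S <- diag(3); S[1, 2] <- S[2, 1] <- 0.4
#' glasso_fit(S, lambda = 0.05)$precision
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 10000, warm = NULL) {
  S <- as.matrix(S)
  if (lambda < 0) abort("lambda must be nonnegative")
  if (max(abs(S - t(S))) > 1e-10) abort("S must be symmetric")
  fit <- .glasso_cpp(S, lambda, tol, as.integer(maxit),
                     warm$covariance, warm$beta)
  if (!fit$converged) {
    abort(paste0("graphical lasso did not converge at lambda = ",
                 signif(lambda, 6), " after ", fit$iterations, " sweeps"))
  }
  dimnames(fit$precision) <- dimnames(S)
  dimnames(fit$covariance) <- dimnames(S)
  fit
}

#' Partial correlations from a precision matrix
#'
#' `w_ij = -k_ij / sqrt(k_ii k_jj)`, with zero diagonal. These are the edge
#' weights of a Gaussian graphical model.
#'
#' @param precision Positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations, diagonal exactly 0.
#' @export
#' @examples
#' precision_to_partial(matrix(c(1, -0.5, -0.5, 1), 2))
precision_to_partial <- function(precision) {
  d <- diag(precision)
  if (any(d <= 0)) abort("precision matrix has a nonpositive diagonal")
  w <- -precision / sqrt(tcrossprod(d))
  diag(w) <- 0
  dimnames(w) <- dimnames(precision)
  w
}

gaussian_loglik <- function(theta, S, n) {
  ld <- determinant(theta, logarithm = TRUE)
  (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
}

#' EBIC-selected graphical-lasso network
#'
#' Fits the graphical lasso along a decreasing penalty path (default 100
#' logarithmically spaced values from `lambda_max`, the largest absolute
#' off-diagonal of `S`, down to `lambda_min_ratio * lambda_max`) and keeps
#' the model minimizing the extended Bayesian information criterion
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)`, where `E` is the
#' number of nonzero edges. Exact EBIC ties are broken toward the larger
#' penalty (sparser model). Edge weights are partial correlations.
#'
#' @param S Positive-definite correlation matrix (e.g. from
#'   [tetrachoric()]).
#' @param n Sample size behind `S`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param lambda Optional explicit decreasing penalty path.
#' @param n_lambda,lambda_min_ratio Path construction parameters.
#' @param edge_tol Absolute weight above which an edge counts as nonzero
#'   (default `1e-10`; the lasso zeros are exact, this guards float noise).
#' @param items Optional item codes (defaults to `colnames(S)`).
#' @return An object of class `symptom_network`: `weights` (partial
#'   correlations, zero diagonal), `precision`, `lambda`, `ebic`, `gamma`,
#'   `n`, `p`, `items`, `nonzero_edges`, `path` (tibble with `lambda`,
#'   `edges`, `ebic`), `edge_tol`.
#' @export
#' @examples
#' x <- simulate_cohort(cohort_spec(500, rep(0.5, 4),
#'        make_planted_network(4, c(2, 2), 0.5)$correlation), seed = 1)
#' ebic_glasso(tetrachoric(x)$rho, n = 500)
ebic_glasso <- function(S, n, gamma = 0.5, lambda = NULL, n_lambda = 100,
                        lambda_min_ratio = 0.01, edge_tol = 1e-10,
                        items = NULL) {
  S <- as.matrix(S)
  p <- ncol(S)
  items <- items %||% colnames(S) %||% paste0("V", seq_len(p))
  dimnames(S) <- list(items, items)
  off <- abs(S[upper.tri(S)])
  if (is.null(lambda)) {
    lambda_max <- max(off)
    if (lambda_max <= 0) lambda_max <- 1e-4
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = n_lambda))
  }
  if (length(lambda) > 1 && any(diff(lambda) >= 0)) {
    abort("lambda path must be strictly decreasing")
  }
  ut <- upper.tri(S)
  warm <- NULL
  best <- NULL
  path_edges <- integer(length(lambda))
  path_ebic <- numeric(length(lambda))
  for (i in seq_along(lambda)) {
    fit <- glasso_fit(S, lambda[i], warm = warm)
    warm <- fit
    w <- precision_to_partial(fit$precision)
    E <- sum(abs(w[ut]) > edge_tol)
    ll <- gaussian_loglik(fit$precision, S, n)
    ebic <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
    path_edges[i] <- E
    path_ebic[i] <- ebic
    # strict '<' keeps the earlier (larger-lambda, sparser) model on ties
    if (is.null(best) || ebic < best$ebic) {
      best <- list(weights = w, precision = fit$precision,
                   lambda = lambda[i], ebic = ebic, edges = E)
    }
  }
  if (n < p && all(path_edges > 0)) {
    warn("all path models are dense and n < p; EBIC selection is unreliable")
  }
  structure(list(weights = best$weights, precision = best$precision,
                 lambda = best$lambda, ebic = best$ebic, gamma = gamma,
                 n = n, p = p, items = items,
                 nonzero_edges = best$edges,
                 path = tibble::tibble(lambda = lambda, edges = path_edges,
                                       ebic = path_ebic),
                 edge_tol = edge_tol),
            class = "symptom_network")
}

#' Estimate a symptom network from binary data
#'
#' Full estimation step: tetrachoric correlation matrix (with PSD repair if
#' needed) followed by the EBIC-selected graphical lasso. The result's edge
#' weights are regularized partial correlations.
#'
#' @inheritParams tetrachoric
#' @inheritParams ebic_glasso
#' @param ... Passed to [ebic_glasso()].
#' @return A `symptom_network` (see [ebic_glasso()]) with the
#'   `tetrachoric_estimate` attached as `$correlations`.
#' @export
#' @examples
#' x <- simulate_cohort(reap_cohort_spec(), seed = 11)
#' net <- symptom_network(x)
#' glance(net)
symptom_network <- function(data, items = NULL, gamma = 0.5, ...) {
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  est <- tetrachoric(x)
  net <- ebic_glasso(est$rho, n = est$n, gamma = gamma,
                     items = attr(x, "items"), ...)
  net$correlations <- est
  net
}

as_weights <- function(x) {
  if (inherits(x, "symptom_network")) return(x$weights)
  w <- as.matrix(x)
  if (max(abs(w - t(w))) > 1e-10) abort("weights must be symmetric")
  diag(w) <- 0
  if (is.null(colnames(w))) {
    dimnames(w) <- list(paste0("V", seq_len(ncol(w))),
                        paste0("V", seq_len(ncol(w))))
  }
  w
}

#' Edge-count summary of a network
#'
#' @param model A `symptom_network` or weights matrix.
#' @param edge_tol Nonzero threshold (default from the model, else 1e-10).
#' @return A tibble with `nonzero`, `possible` (= p(p-1)/2) and `percent`
#'   (one decimal).
#' @export
#' @examples
#' count_edges(matrix(0, 10, 10))  # 0 of 45
count_edges <- function(model, edge_tol = NULL) {
  w <- as_weights(model)
  edge_tol <- edge_tol %||%
    (if (inherits(model, "symptom_network")) model$edge_tol else 1e-10)
  p <- ncol(w)
  possible <- p * (p - 1) / 2
  nonzero <- sum(abs(w[upper.tri(w)]) > edge_tol)
  tibble::tibble(nonzero = nonzero, possible = possible,
                 percent = round_half_up(100 * nonzero / possible, 1))
}

network_edge_list <- function(w, edge_tol = 1e-10, all = FALSE) {
  items <- colnames(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  out <- tibble::tibble(item_i = items[ut[, 1]], item_j = items[ut[, 2]],
                        weight = w[ut])
  if (!all) out <- out[abs(out$weight) > edge_tol, ]
  out
}

#' Strongest associations in a network
#'
#' The `k` nonzero edges with the largest absolute weight, in deterministic
#' order (ties broken lexicographically by item codes).
#'
#' @inheritParams count_edges
#' @param k Number of edges to return (default 3, the usual report size).
#' @return A tibble `item_i`, `item_j`, `weight`.
#' @export
top_associations <- function(model, k = 3, edge_tol = NULL) {
  w <- as_weights(model)
  edge_tol <- edge_tol %||%
    (if (inherits(model, "symptom_network")) model$edge_tol else 1e-10)
  edges <- network_edge_list(w, edge_tol = edge_tol)
  if (k > nrow(edges)) {
    warn(paste0("only ", nrow(edges), " nonzero edges; returning all"))
    k <- nrow(edges)
  }
  edges <- dplyr::arrange(edges, dplyr::desc(abs(.data$weight)),
                          .data$item_i, .data$item_j)
  head(edges, k)
}

network_graph <- function(w, edge_tol = 1e-10) {
  a <- abs(w)
  a[a <= edge_tol] <- 0
  igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Force-directed network layout
#'
#' Fruchterman–Reingold layout with absolute edge weights as attraction
#' strengths, so strongly connected nodes are placed closer together.
#' Deterministic given `seed`.
#'
#' @inheritParams count_edges
#' @param seed Integer seed.
#' @param iterations Number of layout iterations.
#' @return A tibble `item`, `x`, `y` with attributes `seed`, `iterations`.
#' @export
fruchterman_reingold <- function(model, seed = 1, iterations = 500,
                                 edge_tol = NULL) {
  w <- as_weights(model)
  edge_tol <- edge_tol %||%
    (if (inherits(model, "symptom_network")) model$edge_tol else 1e-10)
  g <- network_graph(w, edge_tol)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations,
                               weights = igraph::E(g)$weight)
  out <- tibble::tibble(item = colnames(w), x = xy[, 1], y = xy[, 2])
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iterations
  out
}

#' @export
print.symptom_network <- function(x, ...) {
  ce <- count_edges(x)
  cat("EBIC-glasso symptom network: ", x$p, " nodes, ", ce$nonzero, " of ",
      ce$possible, " edges (", format(ce$percent, nsmall = 1), "%)\n",
      sep = "")
  cat("  lambda = ", signif(x$lambda, 4), ", EBIC = ", signif(x$ebic, 6),
      " (gamma = ", x$gamma, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}
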