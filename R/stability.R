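centrality_vectors <- function(data, items, gamma = 0.5, ...) {
  net <- suppressWarnings(symptom_network(data, items = items,
                                          gamma = gamma, ...))
  ct <- centrality(net)
  list(net = net,
       values = list(strength = setNames(ct$strength, ct$item),
                     closeness = setNames(ct$closeness, ct$item),
                     betweenness = setNames(ct$betweenness, ct$item)))
}

safe_cor <- function(x, y, method) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

cs_interpretation <- function(cs) {
  dplyr::case_when(cs >= 0.5 ~ "preferred",
                   cs >= 0.25 ~ "interpretable",
                   TRUE ~ "none")
}

#' Case-dropping bootstrap stability (CS-coefficient)
#'
#' For each drop proportion, draws `n_boot` subsamples without replacement
#' of size `ceiling((1 - prop) * n)`, re-runs the full estimation pipeline
#' (tetrachoric correlations, EBIC graphical lasso, centrality) on each,
#' and correlates the subsample centralities with the original ones. The
#' CS-coefficient of an index is the largest tested proportion at which at
#' least `prob` of the correlations are `>= cor_threshold`, with all
#' smaller tested proportions also passing; it is 0 when the smallest
#' proportion fails. Correlations that are undefined because either vector
#' has zero variance (e.g. an empty selected network) are recorded as `NA`
#' and count as failures. Proportions are scanned in increasing order and
#' scanning stops once every index has failed, which the monotone
#' definition makes exact.
#'
#' @param data Binary symptom data (`symptom_matrix` or data frame).
#' @param items Symptom columns.
#' @param drop_proportions Increasing proportions in (0, 1); default
#'   `seq(0.05, 0.75, by = 0.05)`, so the CS-coefficient tops out at 0.75.
#' @param n_boot Bootstrap subsamples per proportion (default 1000).
#' @param seed Master seed; per-proportion, per-replicate seeds are derived
#'   from it so any replicate is independently reproducible.
#' @param gamma EBIC hyperparameter for the re-estimated networks.
#' @param cor_method `"pearson"` (default, the toolchain convention) or
#'   `"spearman"` (rank correlation, the verbal definition).
#' @param cor_threshold,prob The stability rule: correlation at least
#'   `cor_threshold` (default 0.7) in at least `prob` (default 0.95) of the
#'   replicates.
#' @param min_rows Minimum subsample size for estimation (default `3 * p`);
#'   smaller replicates are skipped and counted.
#' @param ... Passed to [ebic_glasso()] via [symptom_network()].
#' @return An object of class `stability_report`: `cs` (tibble with
#'   `index`, `cs`, `interpretation`), `table` (one row per replicate:
#'   `prop`, `boot`, `index`, `correlation`), `n_boot`, `seed`,
#'   `n_skipped`, `cor_method`, `params`.
#' @export
#' @examples
#' x <- simulate_cohort(cohort_spec(300, rep(0.5, 4),
#'        make_planted_network(4, c(2, 2), 0.5)$correlation), seed = 2)
#' case_drop_bootstrap(x, drop_proportions = c(0.1, 0.3), n_boot = 10,
#'                     seed = 9)
case_drop_bootstrap <- function(data, items = NULL,
                                drop_proportions = seq(0.05, 0.75, by = 0.05),
                                n_boot = 1000, seed = 1, gamma = 0.5,
                                cor_method = c("pearson", "spearman"),
                                cor_threshold = 0.7, prob = 0.95,
                                min_rows = NULL, ...) {
  cor_method <- match.arg(cor_method)
  if (any(diff(drop_proportions) <= 0) ||
      any(drop_proportions <= 0 | drop_proportions >= 1)) {
    abort("drop_proportions must be strictly increasing within (0, 1)")
  }
  if (n_boot < 1) abort("n_boot must be at least 1")
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  items <- attr(x, "items")
  n <- nrow(x)
  p <- length(items)
  min_rows <- min_rows %||% (3 * p)
  indices <- c("strength", "closeness", "betweenness")

  orig <- centrality_vectors(x, items, gamma = gamma, ...)$values

  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             length(drop_proportions) * n_boot),
                  nrow = length(drop_proportions))
  rows <- list()
  n_skipped <- 0L
  alive <- setNames(rep(TRUE, length(indices)), indices)
  for (i in seq_along(drop_proportions)) {
    prop <- drop_proportions[i]
    size <- ceiling((1 - prop) * n)
    cors <- matrix(NA_real_, n_boot, length(indices),
                   dimnames = list(NULL, indices))
    for (b in seq_len(n_boot)) {
      if (size < min_rows) {
        n_skipped <- n_skipped + 1L
        next
      }
      set.seed(seeds[i, b])
      sub <- x[sample.int(n, size), , drop = FALSE]
      res <- try(centrality_vectors(sub, items, gamma = gamma, ...),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        n_skipped <- n_skipped + 1L
        next
      }
      for (idx in indices) {
        cors[b, idx] <- safe_cor(orig[[idx]], res$values[[idx]], cor_method)
      }
    }
    rows[[i]] <- tibble::tibble(
      prop = prop, boot = rep(seq_len(n_boot), length(indices)),
      index = rep(indices, each = n_boot), correlation = as.vector(cors))
    pass <- colMeans(!is.na(cors) & cors >= cor_threshold) >= prob
    alive <- alive & pass
    if (!any(alive)) break
  }
  table <- dplyr::bind_rows(rows)
  cs <- purrr::map_dfr(indices, function(idx) {
    cs_val <- 0
    for (prop in drop_proportions) {
      sub <- table$correlation[table$prop == prop & table$index == idx]
      if (length(sub) == 0) break
      ok <- mean(!is.na(sub) & sub >= cor_threshold) >= prob
      if (!ok) break
      cs_val <- prop
    }
    tibble::tibble(index = idx, cs = cs_val,
                   interpretation = cs_interpretation(cs_val))
  })
  structure(list(cs = cs, table = table, n_boot = n_boot, seed = seed,
                 n_skipped = n_skipped, cor_method = cor_method,
                 params = list(drop_proportions = drop_proportions,
                               cor_threshold = cor_threshold, prob = prob,
                               gamma = gamma, min_rows = min_rows)),
            class = "stability_report")
}

#' Nonparametric bootstrap difference tests
#'
#' Resamples rows with replacement, re-estimates the network per resample,
#' and computes percentile confidence intervals of the difference for every
#' pair of edge weights and every pair of node strengths; a pair is flagged
#' significant when its interval excludes 0. Resamples in which any item is
#' constant are skipped and counted.
#'
#' @inheritParams case_drop_bootstrap
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param what Which families of differences to test.
#' @return An object of class `difference_test`: `differences` (tibble
#'   `type`, `a`, `b`, `estimate`, `lower`, `upper`, `significant`),
#'   `n_boot`, `n_skipped`, `seed`, `conf`.
#' @export
difference_bootstrap <- function(data, items = NULL, n_boot = 1000, seed = 1,
                                 gamma = 0.5, conf = 0.95,
                                 what = c("edges", "strength"), ...) {
  if (n_boot < 2) abort("n_boot must be at least 2")
  what <- match.arg(what, several.ok = TRUE)
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  items <- attr(x, "items")
  n <- nrow(x)
  p <- length(items)
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  edge_names <- paste0(items[ut[, 1]], "--", items[ut[, 2]])

  base_net <- suppressWarnings(symptom_network(x, items = items,
                                               gamma = gamma, ...))
  base_edges <- setNames(base_net$weights[upper.tri(base_net$weights)],
                         edge_names)
  base_str <- strength_centrality(base_net)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_boot)
  boot_edges <- matrix(NA_real_, n_boot, length(edge_names),
                       dimnames = list(NULL, edge_names))
  boot_str <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, items))
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    sub <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
    if (any(vapply(items, function(it) {
      m <- mean(sub[[it]])
      m == 0 || m == 1
    }, logical(1)))) {
      n_skipped <- n_skipped + 1L
      next
    }
    net <- suppressWarnings(symptom_network(sub, items = items,
                                            gamma = gamma, ...))
    boot_edges[b, ] <- net$weights[upper.tri(net$weights)]
    boot_str[b, ] <- strength_centrality(net)
  }
  ok <- !is.na(boot_str[, 1])
  alpha <- (1 - conf) / 2

  pair_ci <- function(mat, base, type) {
    nm <- colnames(mat)
    pairs <- which(upper.tri(diag(length(nm))), arr.ind = TRUE)
    purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      d <- mat[ok, i] - mat[ok, j]
      qs <- quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 6)
      tibble::tibble(type = type, a = nm[i], b = nm[j],
                     estimate = base[i] - base[j],
                     lower = qs[1], upper = qs[2],
                     significant = qs[1] > 0 | qs[2] < 0)
    })
  }
  out <- list()
  if ("edges" %in% what) {
    out$edges <- pair_ci(boot_edges, base_edges, "edge")
  }
  if ("strength" %in% what) {
    out$strength <- pair_ci(boot_str, base_str, "strength")
  }
  structure(list(differences = dplyr::bind_rows(out), n_boot = n_boot,
                 n_skipped = n_skipped, seed = seed, conf = conf),
            class = "difference_test")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Case-dropping bootstrap stability (", x$n_boot, " subsamples, ",
      x$cor_method, " correlation)\n", sep = "")
  print(x$cs)
  invisible(x)
}

#' @export
print.difference_test <- function(x, ...) {
  cat("Bootstrap difference test (", x$n_boot, " resamples, ",
      100 * x$conf, "% percentile CIs, ", x$n_skipped, " skipped)\n",
      sep = "")
  cat(sum(x$differences$significant), " of ", nrow(x$differences),
      " pairwise differences significant\n", sep = "")
  invisible(x)
}
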