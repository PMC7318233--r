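#' 2x2 contingency counts for a pair of binary items
#'
#' @param x,y Equal-length binary (0/1) vectors.
#' @return Named integer vector `c(a, b, c, d)`: `a` both present, `b` only
#'   `x` present, `c` only `y` present, `d` both absent.
#' @export
#' @examples
#' pair_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
pair_table <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    abort("x and y must be binary 0/1 vectors")
  }
  c(a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0),
    c = sum(x == 0 & y == 1), d = sum(x == 0 & y == 0))
}

#' Bivariate-normal upper-orthant probability
#'
#' `P(Z1 > h, Z2 > k)` for a standard bivariate normal with correlation
#' `rho`, computed by deterministic Gauss–Legendre quadrature (Genz's BVND
#' scheme, absolute accuracy around 1e-15) — fully reproducible across
#' platforms and runs.
#'
#' @param h,k Thresholds.
#' @param rho Correlation in (-1, 1).
#' @return The orthant probability.
#' @export
#' @examples
#' pbvn_upper(0, 0, 0.5)  # 1/4 + asin(0.5) / (2 * pi)
pbvn_upper <- function(h, k, rho) {
  if (abs(rho) >= 1) abort("rho must lie strictly inside (-1, 1)")
  .bvn_upper_cpp(unname(h), unname(k), unname(rho))
}

tetra_cellprobs <- function(h, k, rho) {
  h <- unname(h)
  k <- unname(k)
  p11 <- unname(pbvn_upper(h, k, rho))
  px <- pnorm(h, lower.tail = FALSE)
  py <- pnorm(k, lower.tail = FALSE)
  p10 <- px - p11
  p01 <- py - p11
  p00 <- 1 - px - p01
  pmax(c(p11 = p11, p10 = p10, p01 = p01, p00 = p00), 1e-320)
}

tetra_loglik <- function(rho, tab, h, k) {
  pr <- tetra_cellprobs(h, k, rho)
  unname(tab["a"] * log(pr["p11"]) + tab["b"] * log(pr["p10"]) +
           tab["c"] * log(pr["p01"]) + tab["d"] * log(pr["p00"]))
}

#' Maximum-likelihood tetrachoric correlation of a 2x2 table
#'
#' Two-step estimator: the two thresholds are fixed at the standard-normal
#' quantiles of the marginal absence proportions, then the latent
#' correlation maximizes the bivariate-normal log-likelihood of the table
#' by bounded one-dimensional optimization over (-0.999, 0.999). When any
#' cell is zero, 0.5 is added to every cell (continuity correction) so the
#' likelihood stays finite. A degenerate margin (an item entirely present
#' or entirely absent) cannot identify the correlation: the pair is flagged
#' and returned with `rho = 0`.
#'
#' @param tab Counts as returned by [pair_table()] (order a, b, c, d).
#' @param correct Continuity-correction constant added to all cells when
#'   any cell is zero (default 0.5).
#' @return A list: `rho`, `thresholds` (length 2), `loglik`, `degenerate`,
#'   `corrected`.
#' @export
#' @examples
#' estimate_tetrachoric(c(a = 40, b = 10, c = 10, d = 40))
estimate_tetrachoric <- function(tab, correct = 0.5) {
  tab <- as.numeric(tab)
  if (length(tab) != 4 || any(tab < 0)) abort("tab must be 4 nonnegative counts")
  names(tab) <- c("a", "b", "c", "d")
  n <- sum(tab)
  if (n < 2) abort("need at least 2 observations")
  px <- (tab["a"] + tab["b"]) / n
  py <- (tab["a"] + tab["c"]) / n
  if (px == 0 || px == 1 || py == 0 || py == 1) {
    warn("degenerate margin (item all-present or all-absent); rho set to 0")
    return(list(rho = 0,
                thresholds = unname(qnorm(1 - c(px, py))),
                loglik = NA_real_, degenerate = TRUE, corrected = FALSE))
  }
  corrected <- any(tab == 0)
  if (corrected) {
    tab <- tab + correct
    n <- sum(tab)
    px <- (tab["a"] + tab["b"]) / n
    py <- (tab["a"] + tab["c"]) / n
  }
  h <- qnorm(1 - px)
  k <- qnorm(1 - py)
  opt <- optimize(tetra_loglik, interval = c(-0.999, 0.999), maximum = TRUE,
                  tab = tab, h = h, k = k, tol = 1e-7)
  list(rho = unname(opt$maximum), thresholds = unname(c(h, k)),
       loglik = unname(opt$objective), degenerate = FALSE,
       corrected = corrected)
}

# clip eigenvalues at `floor`, rebuild, rescale to unit diagonal; iterated
# because the rescaling can push the smallest eigenvalue back under the
# floor slightly
psd_repair <- function(rho, floor = 1e-6, max_pass = 100) {
  for (pass in seq_len(max_pass)) {
    ev <- eigen(rho, symmetric = TRUE)
    if (min(ev$values) >= floor * (1 - 1e-9)) break
    vals <- pmax(ev$values, floor)
    out <- ev$vectors %*% (vals * t(ev$vectors))
    out <- out / sqrt(tcrossprod(diag(out)))
    rho <- (out + t(out)) / 2
  }
  rho
}

#' Tetrachoric correlation matrix of a symptom cohort
#'
#' Estimates all pairwise tetrachoric correlations of the binary items by
#' two-step maximum likelihood (see [estimate_tetrachoric()]). Pairwise ML
#' does not guarantee a positive-definite matrix; when the smallest
#' eigenvalue falls below `floor` the matrix is repaired by clipping
#' eigenvalues at `floor` and rescaling to unit diagonal, and
#' `psd_repaired` is flagged.
#'
#' @param data A `symptom_matrix` or data frame of 0/1 items.
#' @param items Symptom columns (defaults to the validated attribute).
#' @param floor Smallest admissible eigenvalue (default `1e-6`).
#' @param correct Continuity correction passed to [estimate_tetrachoric()].
#' @return An object of class `tetrachoric_estimate`: `rho` (p x p),
#'   `thresholds` (named), `psd_repaired`, `min_eigenvalue` (before any
#'   repair), `n`, `items`, `n_degenerate`.
#' @export
#' @examples
#' x <- simulate_cohort(cohort_spec(400, rep(0.5, 4)), seed = 3)
#' tetrachoric(x)
tetrachoric <- function(data, items = NULL, floor = 1e-6, correct = 0.5) {
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  items <- attr(x, "items")
  p <- length(items)
  n <- nrow(x)
  rho <- diag(p)
  thr <- setNames(numeric(p), items)
  n_degenerate <- 0L
  cols <- lapply(items, function(it) x[[it]])
  for (j in seq_len(p)) thr[j] <- qnorm(1 - mean(cols[[j]]))
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      est <- withCallingHandlers(
        estimate_tetrachoric(pair_table(cols[[j]], cols[[k]]),
                             correct = correct),
        warning = function(w) {
          invokeRestart("muffleWarning")
        })
      if (isTRUE(est$degenerate)) n_degenerate <- n_degenerate + 1L
      rho[j, k] <- rho[k, j] <- min(max(est$rho, -0.999), 0.999)
    }
  }
  dimnames(rho) <- list(items, items)
  min_eig <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- min_eig < floor
  if (repaired) {
    rho <- psd_repair(rho, floor = floor)
    dimnames(rho) <- list(items, items)
  }
  if (n_degenerate > 0) {
    warn(paste0(n_degenerate, " pair(s) with a degenerate margin set to 0"))
  }
  structure(list(rho = rho, thresholds = thr, psd_repaired = repaired,
                 min_eigenvalue = min_eig, n = n, items = items,
                 n_degenerate = n_degenerate),
            class = "tetrachoric_estimate")
}

#' @export
print.tetrachoric_estimate <- function(x, ...) {
  cat("Tetrachoric correlation estimate: ", length(x$items), " items, n = ",
      x$n, "\n", sep = "")
  cat("  min eigenvalue ", signif(x$min_eigenvalue, 4),
      if (x$psd_repaired) " (repaired to PSD)" else "", "\n", sep = "")
  invisible(x)
}
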