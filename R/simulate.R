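#' Latent-Gaussian thresholds for target prevalences
#'
#' Under the latent-Gaussian threshold (probit) model an item is present
#' when its standard-normal latent variable exceeds a threshold, so the
#' threshold for a target presence probability `pi` is `qnorm(1 - pi)`.
#' This is the exact inverse of the marginal step of tetrachoric
#' estimation, which makes simulation-based recovery tests well posed.
#'
#' @param prevalences Numeric vector of target presence probabilities,
#'   strictly inside (0, 1).
#' @return Numeric vector of thresholds, same length and names.
#' @export
#' @examples
#' make_thresholds(c(0.5, 0.732))
make_thresholds <- function(prevalences) {
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("prevalences must lie strictly inside (0, 1)")
  }
  qnorm(1 - prevalences)
}

#' Block-structured latent correlation with known partition
#'
#' Builds a compound-symmetry block correlation matrix: `within` on
#' off-diagonal entries inside each block, `between` across blocks. The
#' implied precision matrix is block-dense / cross-block-zero, so the true
#' edge set (nonzero partial correlations) and the true community partition
#' are known exactly — ground truth for edge-recovery and community tests.
#'
#' @param p Number of nodes.
#' @param blocks Integer vector of block sizes summing to `p`.
#' @param within Latent correlation inside blocks.
#' @param between Latent correlation across blocks (default 0).
#' @return A list of class `planted_network`: `correlation` (p x p),
#'   `partition` (integer vector), `edges` (logical p x p matrix of true
#'   nonzero partial correlations), `partial` (true partial correlations).
#' @export
#' @examples
#' net <- make_planted_network(10, blocks = c(5, 5), within = 0.6)
#' net$partition
make_planted_network <- function(p, blocks, within = 0.6, between = 0) {
  if (sum(blocks) != p) abort("block sizes must sum to p")
  part <- rep(seq_along(blocks), blocks)
  same <- outer(part, part, "==")
  sigma <- ifelse(same, within, between)
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort(paste0("within/between weights give a non-positive-definite ",
                 "correlation matrix (min eigenvalue ", signif(min(ev), 3),
                 "); reduce the weights"))
  }
  prec <- solve(sigma)
  partial <- -prec / sqrt(tcrossprod(diag(prec)))
  diag(partial) <- 0
  edges <- abs(partial) > 1e-8
  diag(edges) <- FALSE
  structure(list(correlation = sigma, partition = part,
                 edges = edges, partial = partial, p = p),
            class = "planted_network")
}

validate_correlation <- function(sigma, p) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != p || ncol(sigma) != p) {
    abort("latent_correlation has the wrong dimension")
  }
  if (max(abs(sigma - t(sigma))) > 1e-12) {
    abort("latent_correlation must be symmetric")
  }
  if (max(abs(diag(sigma) - 1)) > 1e-12) {
    abort("latent_correlation must have unit diagonal")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("latent_correlation must be positive definite")
  sigma
}

#' Specification of a synthetic binary symptom cohort
#'
#' Defines the latent-Gaussian threshold generator: `n` latent draws from a
#' multivariate normal with correlation `latent_correlation` are
#' dichotomized at the thresholds implied by `prevalences`. Optional
#' subgroup cells carry their own size, label values and overrides of the
#' prevalences and/or the latent correlation, so subgroup-contrast analyses
#' have a synthetic analogue with known heterogeneity.
#'
#' @param n Cohort size.
#' @param prevalences Target marginal presence probabilities in (0, 1);
#'   names are used as item codes (defaults to the ICD-10 codes when
#'   `length(prevalences) == 10`, else `V1..Vp`).
#' @param latent_correlation p x p positive-definite correlation matrix
#'   (default identity).
#' @param subgroups Optional list of cells; each cell is a list with
#'   elements `labels` (named character vector, e.g.
#'   `c(region = "East")`), `n`, and optional `prevalences` /
#'   `latent_correlation` overrides. Cell sizes must sum to `n`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, prevalences,
                        latent_correlation = diag(length(prevalences)),
                        subgroups = NULL) {
  p <- length(prevalences)
  if (p < 2) abort("need at least 2 items")
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("prevalences must lie strictly inside (0, 1)")
  }
  codes <- names(prevalences)
  if (is.null(codes)) {
    codes <- if (p == 10) icd10_items()$code else paste0("V", seq_len(p))
  }
  sigma <- validate_correlation(latent_correlation, p)
  if (!is.null(subgroups)) {
    sizes <- vapply(subgroups, function(cell) as.integer(cell$n), integer(1))
    if (sum(sizes) != n) abort("subgroup cell sizes must sum to n")
    for (cell in subgroups) {
      if (!is.null(cell$prevalences) &&
          (length(cell$prevalences) != p ||
           any(cell$prevalences <= 0 | cell$prevalences >= 1))) {
        abort("invalid per-cell prevalence override")
      }
      if (!is.null(cell$latent_correlation)) {
        validate_correlation(cell$latent_correlation, p)
      }
    }
  }
  structure(list(n = as.integer(n), prevalences = setNames(prevalences, codes),
                 latent_correlation = sigma, item_codes = codes,
                 subgroups = subgroups),
            class = "cohort_spec")
}

# synthetic sparse latent structure for the default template: a ring with
# chords over the nine non-AGI symptoms, AGI latently disconnected (an
# analogue of the isolated-psychomotor-disturbance finding). NOT the true
# REAP-AD structure, which is not public.
default_reap_structure <- function() {
  codes <- icd10_items()$code
  p <- 10
  pc <- matrix(0, p, p, dimnames = list(codes, codes))
  link <- function(a, b, v) {
    pc[a, b] <<- v
    pc[b, a] <<- v
  }
  link("SAD", "INT", 0.30); link("INT", "FAT", 0.25)
  link("FAT", "SLE", 0.20); link("SLE", "CON", 0.20)
  link("CON", "SEL", 0.20); link("SEL", "SUI", 0.25)
  link("SUI", "GUI", 0.30); link("GUI", "SAD", 0.20)
  link("SAD", "SLE", 0.15); link("INT", "SUI", 0.20)
  link("FAT", "APE", 0.20); link("SAD", "APE", 0.15)
  prec <- diag(p) - pc          # unit-diagonal precision, -pc off-diagonal
  sigma <- solve(prec)
  sigma <- sigma / sqrt(tcrossprod(diag(sigma)))
  dimnames(sigma) <- list(codes, codes)
  validate_correlation((sigma + t(sigma)) / 2, p)
}

#' Default synthetic REAP-AD cohort template
#'
#' A [cohort_spec()] matching the published study conditions: n = 1174 with
#' four region-by-income cells (East/HIC 403, East/MIC 240,
#' SouthSoutheast/HIC 38, SouthSoutheast/MIC 493) whose prevalence targets
#' are the published region-specific rates, so the pooled marginals equal
#' the published overall rates exactly. The latent correlation defaults to
#' a synthetic sparse structure with AGI disconnected; the true structure
#' behind the published data is unknown.
#'
#' @param latent_correlation Optional replacement latent correlation matrix
#'   (applied to every cell).
#' @return A `cohort_spec`.
#' @export
#' @examples
#' spec <- reap_cohort_spec()
#' cohort <- simulate_cohort(spec, seed = 1)
reap_cohort_spec <- function(latent_correlation = default_reap_structure()) {
  rates <- reap_symptom_rates()
  codes <- icd10_items()$code
  prev_of <- function(ch) {
    r <- rates[rates$cohort == ch, ]
    setNames(r$count[match(codes, r$code)] / r$cohort_n[1], codes)
  }
  cells <- reap_subgroup_cells()
  subgroups <- purrr::pmap(cells, function(region, income, n) {
    list(labels = c(region = region, income = income), n = n,
         prevalences = prev_of(region))
  })
  cohort_spec(n = 1174, prevalences = prev_of("overall"),
              latent_correlation = latent_correlation,
              subgroups = subgroups)
}

simulate_binary <- function(n, prevalences, sigma) {
  p <- length(prevalences)
  thr <- make_thresholds(prevalences)
  z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  y <- matrix(0L, n, p)
  for (j in seq_len(p)) y[, j] <- as.integer(z[, j] > thr[j])
  colnames(y) <- names(prevalences)
  y
}

#' Simulate a binary symptom cohort
#'
#' Draws latent multivariate-normal profiles with the specified correlation
#' and dichotomizes them at the thresholds implied by the target
#' prevalences. Output is exactly reproducible given `seed`; subgroup cells
#' are generated sequentially under one seed stream and tagged with their
#' label columns.
#'
#' @param spec A [cohort_spec()] (default: the REAP-AD template).
#' @param seed Integer seed.
#' @return A `symptom_matrix` tibble (items plus any subgroup columns).
#' @export
#' @examples
#' x <- simulate_cohort(reap_cohort_spec(), seed = 42)
#' prevalence(x)
simulate_cohort <- function(spec = reap_cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  if (is.null(spec$subgroups)) {
    y <- simulate_binary(spec$n, spec$prevalences, spec$latent_correlation)
    out <- tibble::as_tibble(y)
    return(as_symptom_matrix(out, items = spec$item_codes, quiet = TRUE))
  }
  parts <- purrr::map(spec$subgroups, function(cell) {
    prev <- cell$prevalences %||% spec$prevalences
    names(prev) <- spec$item_codes
    sigma <- cell$latent_correlation %||% spec$latent_correlation
    y <- tibble::as_tibble(simulate_binary(cell$n, prev, sigma))
    for (lab in names(cell$labels)) y[[lab]] <- unname(cell$labels[lab])
    y
  })
  out <- dplyr::bind_rows(parts)
  label_cols <- setdiff(names(out), spec$item_codes)
  as_symptom_matrix(out, items = spec$item_codes,
                    subgroups = if (length(label_cols)) label_cols else NULL,
                    quiet = TRUE)
}
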