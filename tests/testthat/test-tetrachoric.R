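test_that("pair_table enumerates the four cells", {
  expect_identical(pair_table(c(1, 1, 0, 0), c(1, 0, 1, 0)),
                   c(a = 1L, b = 1L, c = 1L, d = 1L))
  x <- c(1, 0, 1, 1, 0)
  tab <- pair_table(x, x)
  expect_equal(unname(tab[c("b", "c")]), c(0L, 0L))
  tab2 <- pair_table(x, 1 - x)
  expect_equal(unname(tab2[c("a", "d")]), c(0L, 0L))
  expect_equal(sum(tab), length(x))
  expect_error(pair_table(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("orthant probabilities match closed forms and direct integration", {
  # Sheppard: P(X>0, Y>0) = 1/4 + asin(rho) / (2 pi)
  for (r in c(-0.8, -0.3, 0, 0.5, 0.95)) {
    expect_equal(pbvn_upper(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
  }
  # nested univariate integration as an independent check
  direct <- function(h, k, r) {
    # P(Y > k | X = x) = pnorm((r x - k) / sqrt(1 - r^2))
    integrate(function(x) {
      dnorm(x) * pnorm((r * x - k) / sqrt(1 - r^2))
    }, h, Inf, rel.tol = 1e-12)$value
  }
  for (case in list(c(0.3, -0.4, 0.6), c(-1.2, 0.8, -0.7),
                    c(2.0, 1.5, 0.97), c(0.1, 0.2, -0.99))) {
    expect_equal(pbvn_upper(case[1], case[2], case[3]),
                 direct(case[1], case[2], case[3]), tolerance = 1e-9)
  }
})

test_that("independence table gives rho 0 with zero thresholds", {
  est <- estimate_tetrachoric(c(a = 25, b = 25, c = 25, d = 25))
  expect_equal(est$rho, 0, tolerance = 1e-6)
  expect_equal(est$thresholds, c(0, 0), tolerance = 1e-12)
})

test_that("perfect-association table is pulled to high rho by the correction", {
  est <- estimate_tetrachoric(c(a = 50, b = 0, c = 0, d = 50))
  expect_true(est$corrected)
  expect_gt(est$rho, 0.95)
  oracle <- oracle_grid_tetrachoric(c(50, 0, 0, 50))
  expect_equal(est$rho, oracle, tolerance = 1e-3)
})

test_that("estimator matches the likelihood grid-search oracle", {
  set.seed(31)
  for (rep in 1:40) {
    tab <- as.numeric(rmultinom(1, sample(60:400, 1), runif(4, 0.03, 1)))
    est <- estimate_tetrachoric(tab)
    if (est$degenerate) next
    expect_lt(abs(est$rho - oracle_grid_tetrachoric(tab)), 1e-3)
  }
})

test_that("rho sign follows the odds ratio", {
  set.seed(7)
  for (rep in 1:25) {
    tab <- as.numeric(rmultinom(1, 150, runif(4, 0.05, 1)))
    if (any(tab == 0)) tab <- tab + 0.5
    lor <- log(tab[1] * tab[4] / (tab[2] * tab[3]))
    rho <- estimate_tetrachoric(tab)$rho
    if (abs(lor) > 1e-3) expect_equal(sign(rho), sign(lor))
  }
})

test_that("degenerate margins are flagged and set to zero", {
  expect_warning(est <- estimate_tetrachoric(c(a = 0, b = 0, c = 30, d = 70)),
                 "degenerate")
  expect_equal(est$rho, 0)
  expect_true(est$degenerate)
})

test_that("estimates recover the latent correlation of simulated data", {
  # consistency at n = 50000 for a spread of latent rho and uneven margins
  for (rho in c(-0.5, 0, 0.3, 0.7)) {
    sig <- matrix(c(1, rho, rho, 1), 2)
    set.seed(1000 + round(100 * rho))
    z <- matrix(rnorm(2 * 50000), ncol = 2) %*% chol(sig)
    x <- as.integer(z[, 1] > make_thresholds(0.6))
    y <- as.integer(z[, 2] > make_thresholds(0.35))
    est <- estimate_tetrachoric(pair_table(x, y))
    expect_lt(abs(est$rho - rho), 0.02)
  }
})

test_that("correlation matrix is symmetric with unit diagonal and matches the scalar path", {
  x <- simulate_cohort(cohort_spec(800, c(A = 0.4, B = 0.6),
                                   matrix(c(1, 0.5, 0.5, 1), 2)), seed = 8)
  est <- tetrachoric(x)
  expect_equal(est$rho, t(est$rho))
  expect_equal(unname(diag(est$rho)), rep(1, 2))
  scalar <- estimate_tetrachoric(pair_table(x$A, x$B))
  expect_equal(est$rho[1, 2], scalar$rho, tolerance = 1e-12)
})

test_that("identity-structure data yield near-zero correlations without repair", {
  x <- simulate_cohort(cohort_spec(50000, rep(0.5, 4)), seed = 44)
  est <- tetrachoric(x)
  off <- est$rho[upper.tri(est$rho)]
  expect_lt(max(abs(off)), 0.03)
  expect_false(est$psd_repaired)
})

test_that("duplicated items trigger PSD repair and a PD result", {
  set.seed(9)
  a <- rbinom(200, 1, 0.5)
  b <- rbinom(200, 1, 0.4)
  x <- tibble::tibble(A = a, B = a, C = b, D = as.integer(xor(a, b)))
  # duplicated items push the smallest eigenvalue to ~1 - 0.999
  est <- tetrachoric(x, items = c("A", "B", "C", "D"), floor = 0.01)
  expect_true(est$psd_repaired)
  expect_lt(est$min_eigenvalue, 0.01)
  ev <- eigen(est$rho, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0.01 * (1 - 1e-8))
  expect_equal(unname(diag(est$rho)), rep(1, 4))
})
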