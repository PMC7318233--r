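test_that("identity input gives identity precision and no edges at any lambda", {
  S <- diag(4)
  for (lam in c(0, 0.1, 0.5)) {
    fit <- glasso_fit(S, lam)
    expect_equal(fit$precision, diag(4), tolerance = 1e-8)
  }
  net <- ebic_glasso(S, n = 100)
  expect_equal(net$nonzero_edges, 0L)
  expect_true(all(net$path$edges == 0))
})

test_that("penalty at or above max |S_ij| kills every edge", {
  S <- random_correlation(5, seed = 3)
  lam <- max(abs(S[upper.tri(S)]))
  fit <- glasso_fit(S, lam * 1.0001)
  off <- fit$precision[upper.tri(fit$precision)]
  expect_true(all(off == 0))
})

test_that("glasso matches a generic optimizer on 3-node problems", {
  set.seed(17)
  for (rep in 1:8) {
    S <- random_correlation(3)
    for (lam in c(0.02, 0.1, 0.3)) {
      fit <- glasso_fit(S, lam)
      mine <- glasso_objective(fit$precision, S, lam)
      oracle <- oracle_glasso_3node(S, lam, seed = rep)$objective
      expect_gte(mine, oracle - 1e-6)
    }
  }
})

test_that("precision PD along the path and edge count is monotone in lambda", {
  x <- simulate_cohort(cohort_spec(
    2000, rep(0.5, 6), make_planted_network(6, c(3, 3), 0.5)$correlation),
    seed = 21)
  S <- tetrachoric(x)$rho
  lam_max <- max(abs(S[upper.tri(S)]))
  lambdas <- exp(seq(log(lam_max), log(0.01 * lam_max), length.out = 30))
  warm <- NULL
  edges <- integer(0)
  for (lam in lambdas) {
    fit <- glasso_fit(S, lam, warm = warm)
    warm <- fit
    ev <- eigen(fit$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    w <- precision_to_partial(fit$precision)
    edges <- c(edges, sum(abs(w[upper.tri(w)]) > 1e-10))
  }
  expect_true(all(diff(edges) >= 0))  # lambda decreasing -> edges grow
})

test_that("partial correlations follow the closed form and stay inside (-1,1)", {
  expect_equal(precision_to_partial(matrix(c(1, -0.5, -0.5, 1), 2))[1, 2], 0.5)
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  set.seed(5)
  for (rep in 1:10) {
    K <- solve(random_correlation(5))
    w <- precision_to_partial(K)
    expect_equal(w, t(w))
    expect_true(all(abs(w[upper.tri(w)]) < 1))
    expect_equal(unname(diag(w)), rep(0, 5))
  }
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)),
               "nonpositive diagonal")
})

test_that("EBIC selection recovers a planted sparse structure", {
  planted <- make_planted_network(10, c(4, 3, 3), within = 0.5)
  x <- simulate_cohort(cohort_spec(5000, rep(0.5, 10), planted$correlation),
                       seed = 77)
  net <- symptom_network(x)
  truth <- planted$edges[upper.tri(planted$edges)]
  found <- abs(net$weights[upper.tri(net$weights)]) > net$edge_tol
  sens <- sum(found & truth) / sum(truth)
  fpr <- sum(found & !truth) / sum(!truth)
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.2)
})

test_that("degenerate single-lambda path returns that lambda", {
  S <- random_correlation(4, seed = 11)
  net <- ebic_glasso(S, n = 500, lambda = 0.1)
  expect_equal(net$lambda, 0.1)
})

test_that("edge counts reproduce the published arithmetic", {
  w <- matrix(0, 10, 10)
  expect_equal(count_edges(w)$possible, 45)
  expect_equal(count_edges(w)$percent, 0)
  # 29 of 45 -> 64.4%
  ut <- which(upper.tri(w))
  w[ut[1:29]] <- 0.1
  w <- w + t(w)
  ce <- count_edges(w)
  expect_equal(ce$nonzero, 29)
  expect_equal(ce$percent, 64.4)
})

test_that("top associations are ordered with lexicographic tie-break", {
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  w["A", "D"] <- w["D", "A"] <- 0.5
  w["B", "C"] <- w["C", "B"] <- -0.5
  w["A", "B"] <- w["B", "A"] <- 0.9
  top <- top_associations(w, 3)
  expect_equal(top$item_i[1], "A")
  expect_equal(top$item_j[1], "B")
  # |0.5| tie: A--D before B--C lexicographically
  expect_equal(top$item_i[2:3], c("A", "B"))
  expect_warning(all4 <- top_associations(w, 10), "3 nonzero")
  expect_equal(nrow(all4), 3)
})

test_that("strong edges pull nodes closer in the layout, deterministically", {
  mk <- function(wt) {
    w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    w[1, 2] <- w[2, 1] <- wt
    w[3, 4] <- w[4, 3] <- 0.05
    w
  }
  strong <- fruchterman_reingold(mk(0.9), seed = 42)
  weak <- fruchterman_reingold(mk(0.05), seed = 42)
  dist12 <- function(l) sqrt(sum((l[1, c("x", "y")] - l[2, c("x", "y")])^2))
  expect_lt(dist12(strong), dist12(weak))
  again <- fruchterman_reingold(mk(0.9), seed = 42)
  expect_identical(strong, again)
  # empty network: repulsion only, all nodes distinct
  empty <- fruchterman_reingold(matrix(0, 3, 3), seed = 1)
  expect_gt(min(dist(cbind(empty$x, empty$y))), 0)
})

test_that("identical pipeline inputs give identical networks", {
  x <- simulate_cohort(reap_cohort_spec(), seed = 55)
  a <- symptom_network(x)
  b <- symptom_network(x)
  expect_identical(a$weights, b$weights)
  expect_identical(a$lambda, b$lambda)
})
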