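star_graph <- function() {
  w <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  w[1, 2:5] <- w[2:5, 1] <- 0.5
  w
}

path_graph <- function() {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  w
}

test_that("strength is the (absolute) sum of incident weights", {
  w <- star_graph()
  s <- strength_centrality(w)
  expect_equal(unname(s), c(2, 0.5, 0.5, 0.5, 0.5))
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 0.3
  w2[1, 3] <- w2[3, 1] <- -0.4
  expect_equal(strength_centrality(w2)[1], 0.7, ignore_attr = TRUE)
  expect_equal(strength_centrality(w2, signed = TRUE)[1], -0.1,
               ignore_attr = TRUE)
  # disconnected node has zero strength
  w3 <- star_graph()
  w3[, 5] <- w3[5, ] <- 0
  expect_equal(unname(strength_centrality(w3)["E"]), 0)
})

test_that("path-graph closeness and betweenness follow the distance arithmetic", {
  w <- path_graph()
  # d(A,B) = 2, d(A,C) = 4
  cl <- closeness_centrality(w)
  expect_equal(unname(cl["A"]), 1 / 6)
  expect_equal(unname(cl["B"]), 1 / 4)
  expect_gt(cl["B"], cl["A"])
  b <- betweenness_centrality(w)
  expect_equal(unname(b), c(0, 1, 0))
})

test_that("isolated nodes get closeness 0 and complete graphs have zero betweenness", {
  w <- star_graph()
  w[, 5] <- w[5, ] <- 0
  expect_equal(unname(closeness_centrality(w)["E"]), 0)
  wc <- matrix(0.4, 5, 5)
  diag(wc) <- 0
  expect_equal(unname(betweenness_centrality(wc)), rep(0, 5))
})

test_that("closeness and betweenness match exhaustive path-enumeration oracles", {
  for (s in c(2, 13, 27)) {
    w <- random_weights(6, density = 0.6, seed = s)
    expect_equal(unname(closeness_centrality(w)), oracle_closeness(w),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(w)), oracle_betweenness(w),
                 tolerance = 1e-8)
  }
})

test_that("centralities are permutation equivariant", {
  w <- random_weights(7, density = 0.5, seed = 5)
  ct <- centrality(w)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  wp <- w[perm, perm]
  ctp <- centrality(wp)
  m <- match(ct$item, ctp$item)
  expect_equal(ct$strength, ctp$strength[m])
  expect_equal(ct$closeness, ctp$closeness[m])
  expect_equal(ct$betweenness, ctp$betweenness[m])
})

test_that("unit-weight graphs reduce to the classical definitions", {
  # 4-cycle with unit weights: classical closeness 3/4, betweenness 0.5
  w <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    w[e[1], e[2]] <- w[e[2], e[1]] <- 1
  }
  expect_equal(unname(closeness_centrality(w)), rep(1 / 4, 4))
  expect_equal(unname(betweenness_centrality(w)), rep(0.5, 4))
})

test_that("adding an edge never decreases endpoint strength", {
  set.seed(3)
  for (rep in 1:10) {
    w <- random_weights(5, 0.5)
    off <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    if (nrow(off) == 0) next
    e <- off[1, ]
    w2 <- w
    w2[e[1], e[2]] <- w2[e[2], e[1]] <- runif(1, -1, 1)
    expect_gte(strength_centrality(w2)[e[1]], strength_centrality(w)[e[1]])
    expect_gte(strength_centrality(w2)[e[2]], strength_centrality(w)[e[2]])
  }
})

test_that("z-scores standardize and ranks are dense with shared ties", {
  w <- star_graph()
  ct <- centrality(w)
  expect_equal(mean(ct$strength_z), 0, tolerance = 1e-12)
  expect_equal(sd(ct$strength_z), 1, tolerance = 1e-12)
  expect_equal(ct$strength_rank, c(1L, 2L, 2L, 2L, 2L))
  # constant index -> z all zero
  wc <- matrix(0.4, 4, 4)
  diag(wc) <- 0
  expect_equal(centrality(wc)$strength_z, rep(0, 4))
})

test_that("top-3 summary orders by value with lexicographic tie-break", {
  ct <- centrality(star_graph())
  top <- summarize_top3(ct)
  s <- top[top$index == "strength", ]
  expect_equal(s$item, c("A", "B", "C"))  # B-E tie -> lexicographic
  expect_equal(s$value[1], 2)
  # planted star: center first on every index
  expect_equal(top$item[top$rank == 1], rep("A", 3))
})
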