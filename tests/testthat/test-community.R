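brute_force_best <- function(w, gamma = 0.5) {
  parts <- all_partitions(ncol(w))
  energies <- vapply(parts, function(m) network_hamiltonian(w, m, gamma),
                     numeric(1))
  list(energy = min(energies), partition = parts[[which.min(energies)]],
       energies = energies, partitions = parts)
}

two_cliques <- function(wt = 0.5) {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- wt
  w[4:6, 4:6] <- wt
  diag(w) <- 0
  dimnames(w) <- list(paste0("V", 1:6), paste0("V", 1:6))
  w
}

test_that("one community beats singletons on a positive clique", {
  w <- matrix(0.4, 5, 5)
  diag(w) <- 0
  expect_lt(network_hamiltonian(w, rep(1, 5)),
            network_hamiltonian(w, 1:5))
  expect_equal(network_hamiltonian(w, 1:5), 0)
})

test_that("true partition of two disconnected cliques is the exhaustive optimum", {
  w <- two_cliques()
  bf <- brute_force_best(w)
  true_part <- rep(1:2, each = 3)
  expect_equal(network_hamiltonian(w, true_part), bf$energy)
  # strictly better than any other partition
  others <- !vapply(bf$partitions, function(m) {
    symptomnet:::same_partition(m, true_part)
  }, logical(1))
  expect_true(all(bf$energies[others] > bf$energy + 1e-12))
})

test_that("empty network has partition-independent energy", {
  w <- matrix(0, 5, 5)
  parts <- all_partitions(5)
  es <- vapply(parts, function(m) network_hamiltonian(w, m, 0.5), numeric(1))
  expect_true(all(es == 0))
})

test_that("annealing recovers planted blocks in at least 95 of 100 seeded runs", {
  planted <- make_planted_network(10, c(5, 5), within = 0.6)
  x <- simulate_cohort(cohort_spec(5000, rep(0.5, 10), planted$correlation),
                       seed = 301)
  net <- symptom_network(x)
  hits <- 0
  for (s in 1:100) {
    part <- spinglass_communities(net, seed = s)
    hits <- hits + symptomnet:::same_partition(part$membership,
                                               planted$partition)
  }
  expect_gte(hits, 95)
})

test_that("annealing reaches the exhaustive optimum on small graphs", {
  graphs <- list(two_cliques(),
                 two_cliques(0.3) + random_weights(6, 0.2, seed = 2) * 0.1,
                 random_weights(6, 0.5, seed = 4),
                 random_weights(5, 0.7, seed = 6),
                 abs(random_weights(6, 0.9, seed = 8)))
  for (g in seq_along(graphs)) {
    w <- graphs[[g]]
    diag(w) <- 0
    bf <- brute_force_best(w)
    hits <- 0
    for (s in 1:100) {
      part <- spinglass_communities(w, seed = 1000 * g + s)
      expect_lte(part$hamiltonian, 0 + 1e-12)  # never above singletons
      hits <- hits + (part$hamiltonian <= bf$energy + 1e-9)
    }
    expect_gte(hits, 95)
  }
})

test_that("uniform positive complete graph collapses to one community", {
  w <- matrix(0.4, 8, 8)
  diag(w) <- 0
  part <- spinglass_communities(w, gamma = 0.5, seed = 77)
  expect_equal(part$n_communities, 1)
})

test_that("spins parameter caps the number of communities", {
  w <- random_weights(6, 0.5, seed = 10)
  part <- spinglass_communities(w, spins = 2, seed = 3)
  expect_lte(part$n_communities, 2)
  expect_true(all(part$membership %in% 1:2))
})

test_that("community ids are contiguous and label-permutation comparisons work", {
  w <- two_cliques()
  part <- spinglass_communities(w, seed = 5)
  expect_equal(sort(unique(unname(part$membership))),
               seq_len(part$n_communities))
  expect_true(symptomnet:::same_partition(c(2, 2, 2, 7, 7, 7),
                                          c(1, 1, 1, 2, 2, 2)))
  expect_false(symptomnet:::same_partition(c(1, 1, 2, 2), c(1, 2, 1, 2)))
})

test_that("agreement with an independent spin-glass implementation on clean blocks", {
  w <- two_cliques()
  w[1, 4] <- w[4, 1] <- 0.05  # weak bridge (reference needs connectivity)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(1)
  ref <- igraph::cluster_spinglass(g, spins = 6, gamma = 0.5)
  part <- spinglass_communities(w, seed = 2)
  expect_true(symptomnet:::same_partition(part$membership,
                                          igraph::membership(ref)))
})

test_that("isolated nodes are flagged and the largest cluster is reported", {
  # planted 9 + 1: node 10 disconnected
  w <- matrix(0.3, 10, 10)
  w[10, ] <- w[, 10] <- 0
  diag(w) <- 0
  dimnames(w) <- list(paste0("V", 1:10), paste0("V", 1:10))
  part <- spinglass_communities(w, seed = 4)
  ann <- isolate_outliers(w, part)
  expect_true(ann$isolated["V10"])
  expect_equal(sum(ann$isolated), 1L)
  expect_equal(ann$largest_cluster_size, 9)
  expect_setequal(ann$largest_cluster, paste0("V", 1:9))
  # fully connected graph: nothing isolated
  w2 <- matrix(0.3, 4, 4)
  diag(w2) <- 0
  part2 <- spinglass_communities(w2, seed = 4)
  expect_equal(sum(isolate_outliers(w2, part2)$isolated), 0L)
})
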