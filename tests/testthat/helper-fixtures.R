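# Latent structure with heterogeneous node strengths (a weighted chain with
# one chord), so centrality orderings are well separated and stability
# checks are informative.
chain_correlation <- function() {
  pc <- matrix(0, 6, 6)
  edges <- list(c(1, 2, 0.40), c(2, 3, 0.35), c(3, 4, 0.30),
                c(4, 5, 0.25), c(5, 6, 0.20), c(1, 3, 0.20))
  for (e in edges) {
    pc[e[1], e[2]] <- pc[e[2], e[1]] <- e[3]
  }
  sigma <- solve(diag(6) - pc)
  sigma <- sigma / sqrt(tcrossprod(diag(sigma)))
  (sigma + t(sigma)) / 2
}

structured_cohort <- function(n, seed = 66) {
  simulate_cohort(cohort_spec(n, rep(0.5, 6), chain_correlation()),
                  seed = seed)
}
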