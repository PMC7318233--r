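# coupling matrix of the signed spin-glass model: observed weight minus
# gamma times a configuration null based on absolute strengths
spinglass_coupling <- function(w, gamma) {
  s <- rowSums(abs(w))
  tw <- sum(s)                       # = 2 * total absolute weight
  null <- if (tw > 0) tcrossprod(s) / tw else matrix(0, nrow(w), ncol(w))
  m <- w - gamma * null
  diag(m) <- 0
  m
}

#' Spin-glass Hamiltonian of a partition
#'
#' Signed-network Reichardt–Bornholdt energy: for every within-community
#' pair the observed weight is rewarded and a configuration null model
#' (absolute-strength product over total absolute weight, scaled by the
#' resolution `gamma`) is penalized, so negative or missing within-community
#' links raise the energy. Lower is better; the all-singleton partition has
#' energy 0.
#'
#' @param weights Symmetric signed weight matrix (or `symptom_network`).
#' @param membership Integer community assignment, one entry per node.
#' @param gamma Resolution parameter (default 0.5).
#' @return Scalar energy.
#' @export
#' @examples
#' w <- make_planted_network(6, c(3, 3), 0.5)$partial
#' network_hamiltonian(w, rep(1:2, each = 3))
network_hamiltonian <- function(weights, membership, gamma = 0.5) {
  w <- as_weights(weights)
  if (length(membership) != ncol(w)) abort("membership has the wrong length")
  m <- spinglass_coupling(w, gamma)
  same <- outer(membership, membership, "==")
  -sum(m[same & upper.tri(m)])
}

relabel_contiguous <- function(membership) {
  match(membership, unique(membership))
}

# energy change of moving node v to community `to`, given coupling m
move_delta <- function(m, membership, v, to) {
  from <- membership[v]
  if (to == from) return(0)
  others <- seq_along(membership) != v
  sum(m[v, others & membership == from]) -
    sum(m[v, others & membership == to])
}

greedy_polish <- function(m, membership, q) {
  p <- length(membership)
  repeat {
    improved <- FALSE
    for (v in seq_len(p)) {
      deltas <- vapply(seq_len(q), function(s) move_delta(m, membership, v, s),
                       numeric(1))
      best <- which.min(deltas)
      if (deltas[best] < -1e-12) {
        membership[v] <- best
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  membership
}

#' Spin-glass community detection by simulated annealing
#'
#' Minimizes the signed spin-glass Hamiltonian ([network_hamiltonian()]) by
#' single-spin Metropolis updates under geometric cooling (the published
#' schedule: start temperature 1, stop temperature 0.01, cooling factor
#' 0.99, at most `spins` states — capped at the number of nodes), followed
#' by a greedy single-move descent. The all-one and, when possible, the
#' all-singleton partitions are always evaluated as baseline candidates, so
#' the returned energy never exceeds either. Reproducible given `seed`.
#'
#' @param model A `symptom_network` or symmetric weights matrix.
#' @param gamma Resolution parameter (default 0.5).
#' @param spins Maximum number of communities (default 17; effective cap is
#'   the number of nodes).
#' @param start_temp,stop_temp,cooling Annealing schedule.
#' @param sweeps Metropolis sweeps per temperature (default 5).
#' @param restarts Independent annealing restarts; best energy kept.
#' @param seed Integer seed (optional).
#' @return An object of class `community_partition`: `membership` (named,
#'   contiguous ids from 1), `n_communities`, `hamiltonian`, `params`,
#'   `seed`.
#' @export
#' @examples
#' net <- make_planted_network(8, c(4, 4), 0.5)
#' spinglass_communities(net$partial, seed = 1)
spinglass_communities <- function(model, gamma = 0.5, spins = 17,
                                  start_temp = 1, stop_temp = 0.01,
                                  cooling = 0.99, sweeps = 5, restarts = 1,
                                  seed = NULL) {
  w <- as_weights(model)
  p <- ncol(w)
  if (p < 2) abort("need at least 2 nodes")
  q <- min(spins, p)
  m <- spinglass_coupling(w, gamma)
  energy <- function(mem) -sum(m[outer(mem, mem, "==") & upper.tri(m)])
  if (!is.null(seed)) set.seed(seed)

  best_mem <- rep(1L, p)              # all-one baseline
  best_e <- energy(best_mem)
  if (q >= p) {
    e_single <- 0                      # singleton partition: no shared pairs
    if (e_single < best_e) {
      best_mem <- seq_len(p)
      best_e <- e_single
    }
  }

  for (r in seq_len(restarts)) {
    mem <- sample.int(q, p, replace = TRUE)
    e <- energy(mem)
    if (e < best_e) { best_e <- e; best_mem <- mem }
    temp <- start_temp
    while (temp > stop_temp) {
      for (sw in seq_len(sweeps)) {
        for (v in sample.int(p)) {
          to <- sample.int(q, 1)
          if (to == mem[v]) next
          d <- move_delta(m, mem, v, to)
          if (d < 0 || runif(1) < exp(-d / temp)) {
            mem[v] <- to
            e <- e + d
            if (e < best_e - 1e-15) { best_e <- e; best_mem <- mem }
          }
        }
      }
      temp <- temp * cooling
    }
    mem <- greedy_polish(m, mem, q)
    e <- energy(mem)
    if (e < best_e) { best_e <- e; best_mem <- mem }
  }
  best_mem <- greedy_polish(m, best_mem, q)
  best_e <- energy(best_mem)
  mem <- relabel_contiguous(best_mem)
  structure(list(
    membership = setNames(as.integer(mem), colnames(w)),
    n_communities = max(mem), hamiltonian = best_e,
    params = list(gamma = gamma, spins = spins, start_temp = start_temp,
                  stop_temp = stop_temp, cooling = cooling, sweeps = sweeps,
                  restarts = restarts),
    seed = seed), class = "community_partition")
}

#' Flag isolated nodes and report the largest cluster
#'
#' Nodes whose total absolute connection weight falls below `tol` are
#' flagged as isolated outliers; the largest community and its members are
#' reported alongside.
#'
#' @param model A `symptom_network` or weights matrix.
#' @param partition A `community_partition` from [spinglass_communities()].
#' @param tol Strength below which a node counts as isolated.
#' @return The partition, annotated with `isolated` (named logical),
#'   `largest_cluster` (member codes) and `largest_cluster_size`.
#' @export
isolate_outliers <- function(model, partition, tol = 1e-10) {
  w <- as_weights(model)
  stopifnot(inherits(partition, "community_partition"))
  strength <- rowSums(abs(w))
  partition$isolated <- setNames(strength < tol, colnames(w))
  sizes <- table(partition$membership)
  big <- as.integer(names(sizes)[which.max(sizes)])
  partition$largest_cluster <- names(partition$membership)[
    partition$membership == big]
  partition$largest_cluster_size <- length(partition$largest_cluster)
  partition
}

# TRUE when two assignments induce the same partition (labels ignored)
same_partition <- function(a, b) {
  identical(relabel_contiguous(a), relabel_contiguous(b))
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Spin-glass partition: ", x$n_communities, " communities, energy ",
      signif(x$hamiltonian, 6), "\n", sep = "")
  print(split(names(x$membership), x$membership))
  invisible(x)
}
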