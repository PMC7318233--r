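# Independent oracles used across the test suite. Each reimplements the
# quantity it checks by a different route than the package (enumeration,
# brute force, generic optimization, or a different quadrature), so
# agreement is informative.

# --- tetrachoric grid-search oracle -----------------------------------------
# Upper-orthant probabilities for every rho on a fine grid at once, via the
# Plackett identity d/drho P(X>h, Y>k) = bvn density at (h, k), integrated
# by cumulative trapezoid from rho = 0. Independent of the package's
# Gauss-Legendre orthant routine.
oracle_orthant_grid <- function(h, k, rho_grid) {
  stopifnot(!is.unsorted(rho_grid))
  dens <- function(t) {
    exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) /
      (2 * pi * sqrt(1 - t^2))
  }
  base <- pnorm(h, lower.tail = FALSE) * pnorm(k, lower.tail = FALSE)
  f <- dens(rho_grid)
  cum <- c(0, cumsum(diff(rho_grid) * (f[-length(f)] + f[-1]) / 2))
  i0 <- which.min(abs(rho_grid))
  # small trapezoid correction from the grid point nearest 0 to exactly 0
  adj <- (0 - rho_grid[i0]) * (dens(rho_grid[i0]) + dens(0)) / 2
  base + (cum - cum[i0] - adj)
}

# maximize the 2x2 table likelihood over a rho grid (step 1e-4 by default)
oracle_grid_tetrachoric <- function(tab, step = 1e-4, correct = 0.5) {
  tab <- as.numeric(tab)
  if (any(tab == 0)) tab <- tab + correct
  n <- sum(tab)
  h <- qnorm(1 - (tab[1] + tab[2]) / n)
  k <- qnorm(1 - (tab[1] + tab[3]) / n)
  grid <- seq(-0.999, 0.999, by = step)
  p11 <- oracle_orthant_grid(h, k, grid)
  px <- pnorm(h, lower.tail = FALSE)
  py <- pnorm(k, lower.tail = FALSE)
  p10 <- px - p11
  p01 <- py - p11
  p00 <- 1 - px - p01
  ll <- tab[1] * log(pmax(p11, 1e-320)) + tab[2] * log(pmax(p10, 1e-320)) +
    tab[3] * log(pmax(p01, 1e-320)) + tab[4] * log(pmax(p00, 1e-320))
  grid[which.max(ll)]
}

# --- set partitions (restricted growth strings) -----------------------------
all_partitions <- function(p) {
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == p) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# --- brute-force shortest-path centralities ---------------------------------
# distances by Floyd-Warshall; betweenness by exhaustive simple-path
# enumeration with fractional credit over ties. Feasible for p <= 7.
oracle_distances <- function(w, edge_tol = 1e-10) {
  p <- ncol(w)
  d <- ifelse(abs(w) > edge_tol, 1 / abs(w), Inf)
  diag(d) <- 0
  for (m in seq_len(p)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
      }
    }
  }
  d
}

oracle_closeness <- function(w, edge_tol = 1e-10) {
  p <- ncol(w)
  d <- oracle_distances(w, edge_tol)
  sapply(seq_len(p), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    (sum(reach) / (p - 1)) / sum(di[reach])
  })
}

oracle_betweenness <- function(w, edge_tol = 1e-10, tol = 1e-9) {
  p <- ncol(w)
  len <- ifelse(abs(w) > edge_tol, 1 / abs(w), Inf)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path, dist) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1]] <<- list(path = path, dist = dist)
        return(invisible())
      }
      for (u in seq_len(p)) {
        if (is.finite(len[v, u]) && !(u %in% path)) {
          walk(c(path, u), dist + len[v, u])
        }
      }
    }
    walk(s, 0)
    found
  }
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_between(s, t)
      if (length(ps) == 0) next
      dists <- vapply(ps, function(x) x$dist, numeric(1))
      dmin <- min(dists)
      shortest <- ps[dists <= dmin + tol]
      for (sp in shortest) {
        inner <- setdiff(sp$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(shortest)
      }
    }
  }
  btw
}

# --- generic-optimizer oracle for the penalized glasso objective ------------
# maximize logdet K - tr(SK) - lambda * sum_offdiag |K_ij| over PD K,
# parameterized through the Cholesky factor (diagonal on log scale).
glasso_objective <- function(K, S, lambda) {
  ld <- determinant(K, logarithm = TRUE)
  as.numeric(ld$modulus) - sum(S * K) - lambda * sum(abs(K - diag(diag(K))))
}

oracle_glasso_3node <- function(S, lambda, n_starts = 8, seed = 1) {
  set.seed(seed)
  unpack <- function(par) {
    L <- matrix(0, 3, 3)
    diag(L) <- exp(par[1:3])
    L[2, 1] <- par[4]
    L[3, 1] <- par[5]
    L[3, 2] <- par[6]
    tcrossprod(L)
  }
  negobj <- function(par) -glasso_objective(unpack(par), S, lambda)
  best <- Inf
  best_par <- NULL
  for (s in seq_len(n_starts)) {
    start <- c(rnorm(3, 0, 0.3), rnorm(3, 0, 0.3))
    opt <- optim(start, negobj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    opt <- optim(opt$par, negobj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (opt$value < best) {
      best <- opt$value
      best_par <- opt$par
    }
  }
  list(K = unpack(best_par), objective = -best)
}

# random positive-definite correlation matrix
random_correlation <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.5
  cov2cor(S)
}

# small random signed weight matrix with exact zeros
random_weights <- function(p, density = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, p, p)
  ut <- which(upper.tri(w))
  on <- sample(ut, size = round(density * length(ut)))
  w[on] <- runif(length(on), -0.5, 0.8)
  w <- w + t(w)
  dimnames(w) <- list(paste0("V", 1:p), paste0("V", 1:p))
  w
}
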