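# Independent brute-force oracles and graph fixtures used across the suite.
# These deliberately avoid the package's own shortest-path machinery: paths
# are enumerated exhaustively, so they are only usable on small graphs.

# All simple paths from src to dst in an adjacency matrix (0 = no edge).
all_simple_paths_bf <- function(W, src, dst) {
  n <- nrow(W)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == dst) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nb in which(W[last, ] != 0)) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(src)
  out
}

path_dist <- function(W, p) sum(1 / W[cbind(p[-length(p)], p[-1])])

# Brute-force salience: enumerate every simple path, keep minimum-distance
# ones (ties within tol), count shortest-path-tree membership per source.
oracle_salience <- function(W, tol = 1e-9) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (src in seq_len(n)) {
    Tm <- matrix(0, n, n)
    for (dst in setdiff(seq_len(n), src)) {
      paths <- all_simple_paths_bf(W, src, dst)
      if (!length(paths)) next
      dists <- vapply(paths, function(p) path_dist(W, p), numeric(1))
      dmin <- min(dists)
      keep <- dists <= dmin + tol * max(1, dmin)
      for (p in paths[keep]) {
        for (k in seq_len(length(p) - 1L)) {
          Tm[p[k], p[k + 1]] <- 1
          Tm[p[k + 1], p[k]] <- 1
        }
      }
    }
    S <- S + Tm
  }
  S / n
}

# Brute-force betweenness with tied-path splitting, normalized by
# (n-1)(n-2)/2. weighted = reciprocal-weight distances, else hop counts.
oracle_betweenness <- function(W, weighted = TRUE) {
  n <- nrow(W)
  b <- numeric(n)
  Wd <- if (weighted) W else (W != 0) * 1
  for (src in seq_len(n - 1)) {
    for (dst in (src + 1):n) {
      paths <- all_simple_paths_bf(W, src, dst)
      if (!length(paths)) next
      dists <- vapply(paths, function(p) path_dist(Wd, p), numeric(1))
      dmin <- min(dists)
      keep <- paths[dists <= dmin + 1e-9 * max(1, dmin)]
      for (p in keep) {
        inner <- setdiff(p, c(src, dst))
        b[inner] <- b[inner] + 1 / length(keep)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Adjusted R^2 of log(p) ~ log(k) computed from closed-form sums only.
oracle_adj_r2 <- function(k, pk) {
  x <- log(k); y <- log(pk); n <- length(x)
  r <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  1 - (1 - r^2) * (n - 1) / (n - 2)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (combined n must stay small).
oracle_wilcox_exact <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); nx <- length(x)
  r <- rank(vals)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  stats <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Random connected weighted graph as a correlation_network; discrete weights
# make shortest-path ties likely.
random_connected_net <- function(n, seed, p = 0.35, discrete = FALSE) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- ut[runif(length(ut)) < p]
    if (length(on) < n - 1) next
    W[on] <- if (discrete) sample(c(0.25, 0.5, 1), length(on), replace = TRUE)
             else runif(length(on), 0.2, 1)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    g <- igraph::graph_from_adjacency_matrix(W != 0, mode = "undirected")
    if (igraph::is_connected(g)) return(correlation_network(W))
  }
}

# Thresholded view of a full weight matrix (keeps every positive edge).
as_sfn <- function(W, subject_id = "s") {
  apply_threshold(correlation_network(W, subject_id = subject_id), 0)
}

# Weight matrices for standard fixtures.
path_W <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  W
}
star_W <- function(leaves, w = 0.8) {
  W <- matrix(0, leaves + 1, leaves + 1)
  W[1, -1] <- W[-1, 1] <- w
  W
}
ring_W <- function(n, neighbors = 4, w = 0.9) {
  W <- matrix(0, n, n)
  for (d in seq_len(neighbors / 2)) {
    for (i in seq_len(n)) {
      j <- ((i + d - 1) %% n) + 1
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}
random_tree_W <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    W[u, v] <- W[v, u] <- runif(1, 0.3, 1)
  }
  W
}
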