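# Independent brute-force oracles used to check the metric suite. These are
# deliberately naive implementations that share no code path with the
# package internals.

# All-pairs shortest path lengths (lengths = 1/weight) by Floyd-Warshall.
fw_distances <- function(m) {
  n <- nrow(m)
  d <- ifelse(m > 0, 1 / m, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(m) {
  d <- fw_distances(m)
  dv <- d[upper.tri(d)]
  mean(ifelse(is.finite(dv), 1 / dv, 0))
}

oracle_char_path_length <- function(m) {
  d <- fw_distances(m)
  dv <- d[upper.tri(d)]
  mean(dv[is.finite(dv)])
}

# Number of shortest i -> v paths for every v, by dynamic programming over
# vertices in increasing distance from i.
count_shortest_paths <- function(m, d, i, tol = 1e-9) {
  n <- nrow(m)
  cnt <- numeric(n)
  cnt[i] <- 1
  ord <- order(d[i, ])
  for (v in ord) {
    if (v == i || !is.finite(d[i, v])) next
    preds <- which(m[, v] > 0)
    for (u in preds) {
      if (abs(d[i, u] + 1 / m[u, v] - d[i, v]) < tol) cnt[v] <- cnt[v] + cnt[u]
    }
  }
  cnt
}

oracle_betweenness <- function(m, tol = 1e-9) {
  n <- nrow(m)
  d <- fw_distances(m)
  counts <- t(vapply(seq_len(n), function(i) count_shortest_paths(m, d, i, tol),
                     numeric(n)))
  bet <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.finite(d[i, j]) || counts[i, j] == 0) next
      for (v in seq_len(n)) {
        if (v == i || v == j) next
        if (abs(d[i, v] + d[v, j] - d[i, j]) < tol) {
          bet[v] <- bet[v] + counts[i, v] * counts[v, j] / counts[i, j]
        }
      }
    }
  }
  bet
}

# Onnela clustering by direct triangle loop.
oracle_clustering <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in nb) for (b in nb) {
      if (a != b) s <- s + (m[i, a] * m[i, b] * m[a, b])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# Subgraph centrality by truncated walk-count series sum_k (A^k)_ii / k!.
oracle_subgraph_centrality <- function(a, kmax = 30) {
  out <- rep(1, nrow(a))  # k = 0 term
  ak <- diag(nrow(a))
  for (k in seq_len(kmax)) {
    ak <- ak %*% a
    out <- out + diag(ak) / factorial(k)
  }
  out
}

# Weighted modularity of an explicit partition at resolution gamma.
oracle_modularity_q <- function(m, membership, gamma = 1) {
  two_m <- sum(m)
  k <- rowSums(m)
  q <- 0
  n <- nrow(m)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + m[i, j] - gamma * k[i] * k[j] / two_m
      }
    }
  }
  q / two_m
}

# Exhaustive warping-path recursion for DTW (independent of the package DP).
oracle_dtw <- function(a, b) {
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(cost)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    cost + best
  }
  rec(length(a), length(b))
}

# Random symmetric nonnegative weighted graph (possibly disconnected).
random_weighted_graph <- function(n, p = 0.5) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  edges <- stats::runif(sum(ut)) < p
  w <- ifelse(edges, stats::runif(sum(ut), 0.1, 1), 0)
  m[ut] <- w
  m + t(m)
}

# Adjusted-free Rand index between two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
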