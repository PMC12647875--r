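# Weighted graph-theory metric suite for normalized connectomes.
#
# Conventions (fixed once, documented in the vignette):
#   - path lengths use the inverse-weight transform, length = 1/w;
#   - weighted clustering is the Onnela geometric-mean triangle intensity
#     on max-normalized weights;
#   - efficiency counts unreachable pairs as 0; characteristic path length
#     averages finite distances only and flags disconnection;
#   - subgraph centrality is computed on the binarized network by default.

# Pairwise shortest-path length matrix with lengths 1/w.
distance_matrix <- function(m) {
  g <- as_weighted_graph(m)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, nrow(m), nrow(m)); diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Node degree and strength
#'
#' Degree is the count of nonzero neighbors; strength is the sum of a
#' node's edge weights.
#'
#' @param m Connectivity matrix.
#' @return A list with per-node `degree` and `strength` plus their `avg_*`
#'   and `max_*` summaries.
#' @export
degree_strength <- function(m) {
  check_connectivity_matrix(m)
  deg <- rowSums(m > 0)
  str <- rowSums(m)
  list(degree = deg, strength = str,
       avg_degree = mean(deg), max_degree = max(deg),
       avg_strength = mean(str), max_strength = max(str))
}

#' Characteristic path length and global efficiency
#'
#' Shortest paths use edge lengths `1/w`. The characteristic path length is
#' the mean of finite pairwise distances (with a `disconnected` flag when
#' any pair is unreachable); global efficiency is the mean inverse distance
#' with unreachable pairs contributing zero.
#'
#' @param m Connectivity matrix.
#' @return A list with `char_path_length`, `global_efficiency` and
#'   `disconnected`.
#' @export
shortest_path_metrics <- function(m) {
  check_connectivity_matrix(m)
  d <- distance_matrix(m)
  dv <- d[upper.tri(d)]
  disconnected <- any(!is.finite(dv))
  finite <- dv[is.finite(dv)]
  cpl <- if (length(finite) == 0) NA_real_ else mean(finite)
  eff <- mean(ifelse(is.finite(dv), 1 / dv, 0))
  list(char_path_length = cpl, global_efficiency = eff,
       disconnected = disconnected)
}

#' Weighted clustering coefficient and local efficiency
#'
#' Clustering uses the geometric-mean triangle intensity of Onnela et al.
#' on weights normalized to `[0, 1]`: node i's coefficient is
#' `sum_jk (w_ij w_ik w_jk)^(1/3) / (k_i (k_i - 1))` with `k_i` the binary
#' degree. Local efficiency of node i is the global efficiency of the
#' subgraph induced by i's neighbors (original weights). Nodes with degree
#' below 2 score 0 on both.
#'
#' @param m Connectivity matrix with weights in `[0, 1]`.
#' @return A list with per-node `clustering` and `local_efficiency` and
#'   their averages.
#' @export
clustering_and_local_efficiency <- function(m) {
  check_connectivity_matrix(m)
  n <- nrow(m)
  deg <- rowSums(m > 0)
  clus <- onnela_clustering(m)
  leff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] > 0)
    if (length(nb) < 2) next
    leff[i] <- shortest_path_metrics(m[nb, nb, drop = FALSE])$global_efficiency
  }
  list(clustering = clus, local_efficiency = leff,
       avg_clustering = mean(clus), avg_local_efficiency = mean(leff))
}

# Per-node Onnela geometric-mean clustering on [0, 1] weights.
onnela_clustering <- function(m) {
  if (max(m) > 1 + 1e-12) {
    stop("weights must be normalized to [0, 1]; call normalize_weights() first",
         call. = FALSE)
  }
  deg <- rowSums(m > 0)
  w13 <- m^(1 / 3)
  tri <- diag(w13 %*% w13 %*% w13)
  ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
}

# One degree-preserving, weight-preserving null: rewire the binary topology
# keeping the degree sequence, then assign the original weight multiset to
# the rewired edges in random order.
rewired_null <- function(m) {
  g <- as_weighted_graph(m)
  w <- igraph::E(g)$weight
  gb <- igraph::delete_edge_attr(g, "weight")
  gb <- igraph::rewire(gb, igraph::keeping_degseq(niter = 10 * igraph::ecount(gb)))
  el <- igraph::as_edgelist(gb, names = FALSE)
  out <- matrix(0, nrow(m), ncol(m))
  wp <- sample(w)
  for (k in seq_len(nrow(el))) {
    out[el[k, 1], el[k, 2]] <- wp[k]
    out[el[k, 2], el[k, 1]] <- wp[k]
  }
  out
}

#' Small-worldness
#'
#' Sigma-style small-worldness: the ratio of clustering to characteristic
#' path length, each normalized by its mean over an ensemble of degree- and
#' weight-preserving rewired null networks:
#' `sigma = (C / <C_null>) / (L / <L_null>)`. Values above 1 indicate
#' small-world structure.
#'
#' @param m Connectivity matrix (normalized weights).
#' @param n_null Number of null networks (default 10).
#' @param seed Integer seed for the null ensemble.
#' @return A list with `sigma`, `C`, `L`, `C_null`, `L_null`.
#' @export
small_worldness <- function(m, n_null = 10, seed = 1) {
  check_connectivity_matrix(m)
  if (n_null < 1) stop("`n_null` must be >= 1", call. = FALSE)
  C <- mean(onnela_clustering(m))
  L <- shortest_path_metrics(m)$char_path_length
  set.seed(derive_seed(seed, 71L))
  Cn <- Ln <- numeric(n_null)
  for (b in seq_len(n_null)) {
    nullm <- rewired_null(m)
    Cn[b] <- mean(onnela_clustering(nullm))
    Ln[b] <- shortest_path_metrics(nullm)$char_path_length
  }
  if (mean(Cn) == 0) stop("null ensemble has zero clustering", call. = FALSE)
  sigma <- (C / mean(Cn)) / (L / mean(Ln))
  list(sigma = sigma, C = C, L = L, C_null = mean(Cn), L_null = mean(Ln))
}

# Greedy single-node refinement of a partition: repeatedly applies the best
# modularity-improving single-node move (to any community or a new
# singleton) until none improves, so returned partitions are locally
# optimal under single-node moves.
refine_partition <- function(m, membership, gamma) {
  s2 <- sum(m)
  k <- rowSums(m)
  memb <- as.integer(membership)
  repeat {
    improved <- FALSE
    for (v in seq_along(memb)) {
      labs <- unique(memb)
      K <- vapply(labs, function(l) sum(k[memb == l]), numeric(1))
      kv_to <- vapply(labs, function(l) sum(m[v, memb == l]), numeric(1))
      a <- match(memb[v], labs)
      Ka_prime <- K[a] - k[v]
      kva <- kv_to[a]  # m[v, v] = 0 so no self-term
      cand_labs <- c(labs, max(labs) + 1L)
      cand_K <- c(K, 0); cand_kv <- c(kv_to, 0)
      dq <- 2 * (cand_kv - kva - gamma * k[v] * (cand_K - Ka_prime) / s2) / s2
      dq[a] <- 0
      # moving to the current community's "stay" is zero by construction;
      # treat K of a candidate equal to current as already containing v
      best <- which.max(dq)
      if (dq[best] > 1e-12) {
        memb[v] <- cand_labs[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  match(memb, unique(memb))
}

#' Weighted modularity via Louvain optimization
#'
#' Runs Louvain community detection at resolution `gamma` with multiple
#' seeded restarts and keeps the partition with the highest modularity Q.
#'
#' @param m Connectivity matrix.
#' @param gamma Resolution parameter (> 0); the lifespan analyses default
#'   to 0.6, selected by [select_gamma()].
#' @param n_restart Number of seeded restarts (default 10).
#' @param seed Integer seed.
#' @return A list with `Q` and `membership`.
#' @export
modularity_louvain <- function(m, gamma = 0.6, n_restart = 10, seed = 1) {
  check_connectivity_matrix(m)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  g <- as_weighted_graph(m)
  if (igraph::ecount(g) == 0) stop("cannot partition an empty graph", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restart)) {
    set.seed(derive_seed(seed, 83L, r))
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    memb <- refine_partition(m, as.integer(igraph::membership(cl)), gamma)
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                            resolution = gamma)
    if (is.null(best) || q > best$Q) {
      best <- list(Q = q, membership = memb)
    }
  }
  best
}

#' Select the modularity resolution by null-model contrast
#'
#' For each gamma on a grid, computes modularity for every matrix in a
#' cohort sample and for density- and degree-preserving rewired nulls, then
#' takes the two-sample Kolmogorov-Smirnov statistic between the observed
#' and null Q distributions. The selected gamma attains the largest KS
#' statistic (most non-random modular structure); ties resolve to the
#' smallest gamma.
#'
#' @param sample_matrices List of connectivity matrices.
#' @param gamma_grid Numeric grid (default `seq(0.2, 2, by = 0.2)`).
#' @param n_null Nulls per matrix (default 1).
#' @param seed Integer seed.
#' @return A list with `selected_gamma`, `ks` (per-gamma statistic) and the
#'   observed/null Q samples.
#' @export
select_gamma <- function(sample_matrices, gamma_grid = seq(0.2, 2, by = 0.2),
                         n_null = 1, seed = 1) {
  stopifnot(length(gamma_grid) >= 1, length(sample_matrices) >= 1)
  gamma_grid <- sort(gamma_grid)
  set.seed(derive_seed(seed, 97L))
  nulls <- unlist(lapply(sample_matrices, function(m) {
    lapply(seq_len(n_null), function(b) rewired_null(m))
  }), recursive = FALSE)
  ks <- rep(NA_real_, length(gamma_grid))
  obs_q <- null_q <- vector("list", length(gamma_grid))
  for (gi in seq_along(gamma_grid)) {
    g <- gamma_grid[gi]
    qo <- vapply(sample_matrices, function(m)
      modularity_louvain(m, gamma = g, n_restart = 3, seed = seed)$Q, numeric(1))
    qn <- vapply(nulls, function(m)
      modularity_louvain(m, gamma = g, n_restart = 3, seed = seed)$Q, numeric(1))
    obs_q[[gi]] <- qo; null_q[[gi]] <- qn
    if (stats::sd(qo) == 0 && stats::sd(qn) == 0 && qo[1] == qn[1]) {
      ks[gi] <- 0
      next
    }
    ks[gi] <- suppressWarnings(stats::ks.test(qo, qn)$statistic)
  }
  sel <- gamma_grid[which.max(ks)]  # which.max takes the first (smallest) tie
  list(selected_gamma = sel, gamma_grid = gamma_grid, ks = ks,
       observed_q = obs_q, null_q = null_q)
}

# Core/periphery fit of a boolean core assignment: cosine similarity
# between the weight vector and the ideal pattern (1 wherever at least one
# endpoint is in the core).
core_periphery_fit <- function(w, core_i, core_j) {
  delta <- as.numeric(core_i | core_j)
  sd2 <- sum(delta)
  if (sd2 == 0) return(0)
  sum(w * delta) / sqrt(sum(w^2) * sd2)
}

#' Core/periphery structure
#'
#' Borgatti-Everett-style discrete core/periphery optimization: the quality
#' q of a boolean core assignment is the cosine similarity between the
#' observed weights and the ideal pattern in which every edge touching the
#' core is present and the periphery is empty. q lies in `[0, 1]`.
#' Optimization is a seeded steepest-ascent label flip search from multiple
#' strength-ranked initializations.
#'
#' @param m Connectivity matrix.
#' @param n_restart Number of restarts (default 5).
#' @param seed Integer seed.
#' @return A list with `q` and boolean `core`.
#' @export
core_periphery <- function(m, n_restart = 5, seed = 1) {
  check_connectivity_matrix(m)
  n <- nrow(m)
  w2 <- sum(m[upper.tri(m)]^2)
  str_rank <- order(rowSums(m), decreasing = TRUE)
  best <- NULL
  set.seed(derive_seed(seed, 101L))
  for (r in seq_len(n_restart)) {
    core <- rep(FALSE, n)
    if (r == 1) {
      core[str_rank[seq_len(max(1, round(n / 4)))]] <- TRUE
    } else {
      core[stats::runif(n) < 0.5] <- TRUE
      if (!any(core)) core[str_rank[1]] <- TRUE
    }
    # S = total weight on core-touching pairs; D = count of such pairs.
    # Flipping node i only changes pairs (i, j) with j in the periphery,
    # so gains are O(n) via each node's weight-sum into the periphery.
    periph_wsum <- as.numeric(m %*% (!core))
    P <- sum(!core)
    S <- sum(m) / 2 - sum(periph_wsum[!core]) / 2
    D <- n * (n - 1) / 2 - P * (P - 1) / 2
    q <- if (D == 0 || w2 == 0) 0 else S / sqrt(w2 * D)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      dS <- ifelse(core, -periph_wsum, periph_wsum)
      dD <- ifelse(core, -P, P - 1)
      newD <- D + dD
      newq <- ifelse(newD <= 0, 0, (S + dS) / sqrt(w2 * newD))
      i_best <- which.max(newq)
      if (newq[i_best] > q + 1e-12) {
        i <- i_best
        S <- S + dS[i]; D <- D + dD[i]
        core[i] <- !core[i]
        P <- P + if (core[i]) -1L else 1L
        q <- newq[i]
        periph_wsum <- as.numeric(m %*% (!core))
        improved <- TRUE
      }
    }
    if (is.null(best) || q > best$q) best <- list(q = q, core = core)
  }
  best
}

#' k-core size
#'
#' Iteratively peels nodes of binary degree below k; reports the node count
#' of the core at the highest k with a nonempty core (the maximal coreness
#' shell), together with that level.
#'
#' @param m Connectivity matrix.
#' @return A list with `size` and `level`.
#' @export
k_core_size <- function(m) {
  check_connectivity_matrix(m)
  g <- as_weighted_graph(m)
  if (igraph::ecount(g) == 0) return(list(size = 0L, level = 0L))
  core <- igraph::coreness(g)
  kmax <- max(core)
  list(size = sum(core >= kmax), level = as.integer(kmax))
}

#' s-core size
#'
#' Weighted analogue of the k-core: nodes with strength below s are peeled
#' iteratively. The reported core is the last nonempty one as s increases
#' through the achievable strength levels; its node count and level are
#' returned.
#'
#' @param m Connectivity matrix.
#' @return A list with `size` and `level` (the strength threshold at which
#'   the reported core still survives).
#' @export
s_core_size <- function(m) {
  check_connectivity_matrix(m)
  cur <- m
  alive <- which(rowSums(cur) > 0)
  if (length(alive) == 0) return(list(size = 0L, level = 0))
  cur <- cur[alive, alive, drop = FALSE]
  level <- 0
  repeat {
    smin <- min(rowSums(cur))
    nxt <- cur
    # peel at s just above the current minimum strength
    repeat {
      st <- rowSums(nxt)
      drop <- st <= smin + 1e-12
      if (!any(drop) || all(drop)) break
      nxt <- nxt[!drop, !drop, drop = FALSE]
    }
    if (nrow(nxt) == 0 || all(rowSums(nxt) <= smin + 1e-12)) {
      return(list(size = nrow(cur), level = smin))
    }
    level <- smin
    cur <- nxt
  }
}

#' Weighted betweenness centrality
#'
#' Fraction-weighted count of shortest paths (lengths `1/w`) passing
#' through each node; unordered source-target pairs, endpoints excluded,
#' equal-length multiplicities split fractionally.
#'
#' @param m Connectivity matrix.
#' @return Per-node betweenness vector.
#' @export
betweenness_centrality <- function(m) {
  check_connectivity_matrix(m)
  g <- as_weighted_graph(m)
  if (igraph::ecount(g) == 0) return(numeric(nrow(m)))
  as.numeric(igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                                 directed = FALSE))
}

#' Subgraph centrality
#'
#' Exponentially weighted sum of closed walks at each node,
#' `SC_i = sum_j v_ij^2 exp(lambda_j)` over the eigen-decomposition of the
#' adjacency matrix. Computed on the binarized thresholded network by
#' default; set `binarize = FALSE` to use weights.
#'
#' @param m Connectivity matrix.
#' @param binarize Use the binarized adjacency (default TRUE).
#' @return Per-node subgraph centrality vector.
#' @export
subgraph_centrality <- function(m, binarize = TRUE) {
  check_connectivity_matrix(m)
  a <- if (binarize) (m > 0) * 1 else m
  e <- eigen(a, symmetric = TRUE)
  as.numeric((e$vectors^2) %*% exp(e$values))
}

#' Compute the full per-subject metric suite
#'
#' Evaluates density, degree/strength summaries, integration (global
#' efficiency, characteristic path length, small-worldness), segregation
#' (modularity, core/periphery, s-core, k-core, local efficiency,
#' clustering) and centrality (betweenness, subgraph centrality) on a
#' normalized weighted network.
#'
#' @param m Connectivity matrix with weights in `[0, 1]`.
#' @param gamma Modularity resolution (default 0.6).
#' @param n_null Small-world null count (default 10).
#' @param seed Integer seed for stochastic components.
#' @return A list with `global` (one-row data.frame of scalar metrics) and
#'   `nodal` (data.frame of per-node degree, strength, clustering, local
#'   efficiency, betweenness, subgraph centrality).
#' @export
compute_metric_suite <- function(m, gamma = 0.6, n_null = 10, seed = 1) {
  check_connectivity_matrix(m)
  ds <- degree_strength(m)
  sp <- shortest_path_metrics(m)
  cl <- clustering_and_local_efficiency(m)
  sw <- small_worldness(m, n_null = n_null, seed = seed)
  mod <- modularity_louvain(m, gamma = gamma, seed = seed)
  cp <- core_periphery(m, seed = seed)
  kc <- k_core_size(m)
  sc <- s_core_size(m)
  btw <- betweenness_centrality(m)
  sgc <- subgraph_centrality(m)
  global <- data.frame(
    density = compute_density(m),
    avg_degree = ds$avg_degree, max_degree = ds$max_degree,
    avg_strength = ds$avg_strength, max_strength = ds$max_strength,
    global_efficiency = sp$global_efficiency,
    char_path_length = sp$char_path_length,
    disconnected = sp$disconnected,
    small_worldness = sw$sigma,
    modularity = mod$Q,
    core_periphery = cp$q,
    s_core = sc$size, k_core = kc$size,
    avg_local_efficiency = cl$avg_local_efficiency,
    avg_clustering = cl$avg_clustering,
    avg_betweenness = mean(btw),
    avg_subgraph_centrality = mean(sgc))
  nodal <- data.frame(node = seq_len(nrow(m)),
                      degree = ds$degree, strength = ds$strength,
                      clustering = cl$clustering,
                      local_efficiency = cl$local_efficiency,
                      betweenness = btw, subgraph_centrality = sgc)
  list(global = global, nodal = nodal)
}

#' Metric table for a cohort
#'
#' Runs [compute_metric_suite()] on every subject and binds the scalar
#' metrics into a tidy table (one row per subject) plus a long nodal table.
#'
#' @param cohort List of subject records with normalized matrices.
#' @param ... Passed to [compute_metric_suite()].
#' @return A list with `global` and `nodal` data.frames, both carrying
#'   `subject_id` and `age`.
#' @export
cohort_metric_table <- function(cohort, ...) {
  res <- lapply(cohort, function(s) {
    ms <- compute_metric_suite(s$matrix, ...)
    ms$global <- cbind(data.frame(subject_id = s$subject_id, age = s$age,
                                  stringsAsFactors = FALSE), ms$global)
    ms$nodal <- cbind(data.frame(subject_id = s$subject_id, age = s$age,
                                 stringsAsFactors = FALSE), ms$nodal)
    ms
  })
  list(global = do.call(rbind, lapply(res, `[[`, "global")),
       nodal = do.call(rbind, lapply(res, `[[`, "nodal")))
}
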