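# Graph-metric suite vs closed forms and brute-force oracles.

test_that("degree and strength summarize weighted adjacency correctly", {
  k4 <- generate_toy_network("complete", 4)
  ds <- degree_strength(k4)
  expect_equal(ds$degree, rep(3, 4))
  expect_equal(ds$strength, rep(3, 4))

  s5 <- generate_toy_network("star", 5)
  ds <- degree_strength(s5)
  expect_equal(ds$strength, c(4, 1, 1, 1, 1))

  m <- matrix(0, 3, 3); m[1, 2] <- 0.5; m[1, 3] <- 0.25
  m <- m + t(m)
  expect_equal(degree_strength(m)$strength[1], 0.75)
})

test_that("path metrics match closed forms on fixtures", {
  tri <- generate_toy_network("ring", 3)
  sp <- shortest_path_metrics(tri)
  expect_equal(sp$char_path_length, 1)
  expect_equal(sp$global_efficiency, 1)

  p3 <- generate_toy_network("path", 3)
  sp <- shortest_path_metrics(p3)
  expect_equal(sp$char_path_length, 4 / 3)
  expect_equal(sp$global_efficiency, 5 / 6)

  e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 0.5
  sp <- shortest_path_metrics(e)
  expect_equal(sp$char_path_length, 2)   # length = 1/w
  expect_equal(sp$global_efficiency, 0.5)

  empty <- matrix(0, 4, 4)
  sp <- shortest_path_metrics(empty)
  expect_equal(sp$global_efficiency, 0)
  expect_true(sp$disconnected)
})

test_that("clustering uses the geometric-mean triangle form", {
  tri <- generate_toy_network("ring", 3)
  expect_equal(clustering_and_local_efficiency(tri)$clustering, rep(1, 3))
  s5 <- generate_toy_network("star", 5)
  expect_equal(clustering_and_local_efficiency(s5)$clustering, rep(0, 5))
  tw <- matrix(0, 3, 3)
  tw[1, 2] <- 1; tw[1, 3] <- 1; tw[2, 3] <- 0.125
  tw <- tw + t(tw)
  expect_equal(clustering_and_local_efficiency(tw)$clustering, rep(0.5, 3))
})

test_that("path, clustering and subgraph metrics match brute-force oracles", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    m <- random_weighted_graph(n, p = 0.5)
    if (all(m == 0)) next
    sp <- shortest_path_metrics(m)
    expect_equal(sp$global_efficiency, oracle_global_efficiency(m),
                 tolerance = 1e-8)
    if (!sp$disconnected) {
      expect_equal(sp$char_path_length, oracle_char_path_length(m),
                   tolerance = 1e-8)
    }
    expect_equal(clustering_and_local_efficiency(m)$clustering,
                 oracle_clustering(m), tolerance = 1e-8)
    expect_equal(betweenness_centrality(m), oracle_betweenness(m),
                 tolerance = 1e-6)
    expect_equal(subgraph_centrality(m),
                 oracle_subgraph_centrality((m > 0) * 1),
                 tolerance = 1e-8)
  }
})

test_that("betweenness matches hand counts on fixtures", {
  expect_equal(betweenness_centrality(generate_toy_network("ring", 3)),
               rep(0, 3))
  expect_equal(betweenness_centrality(generate_toy_network("path", 3)),
               c(0, 1, 0))
  expect_equal(betweenness_centrality(generate_toy_network("star", 5)),
               c(6, 0, 0, 0, 0))
})

test_that("subgraph centrality matches eigen closed forms", {
  k2 <- generate_toy_network("complete", 2)
  expect_equal(subgraph_centrality(k2), rep(cosh(1), 2))
  tri <- generate_toy_network("ring", 3)
  expect_equal(subgraph_centrality(tri),
               rep(exp(2) / 3 + 2 * exp(-1) / 3, 3))
  iso <- matrix(0, 2, 2)
  expect_equal(subgraph_centrality(iso), rep(1, 2))
})

test_that("modularity recovers planted structure and closed forms", {
  tc <- generate_toy_network("two_cliques", 10)
  mod <- modularity_louvain(tc, gamma = 1)
  expect_equal(mod$Q, 0.5)
  expect_equal(length(unique(mod$membership)), 2)

  # single community has Q = 0 at gamma 1
  expect_equal(oracle_modularity_q(tc, rep(1, 10), gamma = 1), 0)

  # planted 3-block SBM: partition matches blocks
  sbm <- generate_toy_network("sbm", 30, block_count = 3,
                              p_within = 0.9, p_between = 0.05, seed = 4)
  blocks <- attr(sbm, "blocks")
  mod <- modularity_louvain(sbm, gamma = 1)
  expect_gte(length(unique(mod$membership)), 3)
  expect_gt(rand_index(mod$membership, blocks), 0.9)

  # Q agrees with the hand-written formula for the returned partition
  expect_equal(mod$Q, oracle_modularity_q(sbm, mod$membership, gamma = 1),
               tolerance = 1e-10)
})

test_that("returned partitions are locally optimal under single-node moves", {
  set.seed(17)
  m <- random_weighted_graph(12, p = 0.5)
  mod <- modularity_louvain(m, gamma = 1)
  labels <- unique(mod$membership)
  for (v in 1:12) {
    for (lab in c(labels, max(labels) + 1)) {
      cand <- mod$membership
      if (cand[v] == lab) next
      cand[v] <- lab
      expect_lte(oracle_modularity_q(m, cand, 1), mod$Q + 1e-10)
    }
  }
})

test_that("gamma selection maximizes the KS contrast against nulls", {
  set.seed(23)
  mats <- lapply(1:4, function(i) {
    m <- generate_toy_network("sbm", 40, block_count = 4,
                              p_within = 0.8, p_between = 0.05, seed = i)
    attr(m, "blocks") <- NULL
    m
  })
  sel <- select_gamma(mats, gamma_grid = c(0.6, 1.0, 1.4), n_null = 2, seed = 5)
  # recompute the argmax independently from the stored samples
  ks <- vapply(seq_along(sel$gamma_grid), function(gi) {
    suppressWarnings(stats::ks.test(sel$observed_q[[gi]],
                                    sel$null_q[[gi]])$statistic)
  }, numeric(1))
  expect_equal(sel$selected_gamma, sel$gamma_grid[which.max(ks)])
  expect_true(all(abs(sel$ks - ks) < 1e-12))

  # identical observed and null samples: KS statistic effectively 0
  one <- select_gamma(mats[1], gamma_grid = 0.8, n_null = 1, seed = 5)
  expect_equal(one$selected_gamma, 0.8)  # single-point grid returns itself
})

test_that("small-worldness is 1 on complete graphs and > 1 on WS rings", {
  k5 <- generate_toy_network("complete", 5)
  expect_equal(small_worldness(k5, n_null = 10, seed = 1)$sigma, 1)

  g <- igraph::sample_smallworld(1, 50, 3, 0.1)
  ws <- as.matrix(igraph::as_adjacency_matrix(g))
  diag(ws) <- 0
  ws[ws > 1] <- 1
  storage.mode(ws) <- "double"
  expect_gt(small_worldness(ws, n_null = 20, seed = 2)$sigma, 1)
})

test_that("k-core and s-core report the last nonempty peel", {
  k5 <- generate_toy_network("complete", 5)
  expect_equal(k_core_size(k5), list(size = 5L, level = 4L))
  p4 <- generate_toy_network("path", 4)
  expect_equal(k_core_size(p4), list(size = 4L, level = 1L))
  s5 <- generate_toy_network("star", 5)
  sc <- s_core_size(s5)
  expect_equal(sc$size, 5L)
  expect_lte(sc$level, 1)
  expect_equal(k_core_size(matrix(0, 3, 3))$size, 0L)
})

test_that("core/periphery optimum matches exhaustive search on small graphs", {
  exhaustive_q <- function(m) {
    n <- nrow(m); ut <- which(upper.tri(m), arr.ind = TRUE)
    w <- m[upper.tri(m)]
    w2 <- sum(w^2)
    best <- 0
    for (k in 1:(2^n - 1)) {
      core <- as.logical(bitwAnd(k, 2^(0:(n - 1))))
      delta <- as.numeric(core[ut[, 1]] | core[ut[, 2]])
      q <- sum(w * delta) / sqrt(w2 * sum(delta))
      best <- max(best, q)
    }
    best
  }
  # ideal block structure: dense core, empty periphery, full core-periphery
  ideal <- matrix(0, 8, 8)
  ideal[1:3, ] <- 1; ideal[, 1:3] <- 1; diag(ideal) <- 0
  ideal[4:8, 4:8] <- 0
  cp <- core_periphery(ideal, seed = 1)
  expect_equal(cp$q, exhaustive_q(ideal), tolerance = 1e-9)
  expect_equal(cp$q, 1)

  k5 <- generate_toy_network("complete", 5)
  expect_equal(core_periphery(k5)$q, 1)  # all-core attains the optimum

  s5 <- generate_toy_network("star", 5)
  cp <- core_periphery(s5)
  expect_true(cp$core[1])               # center belongs to the core
  expect_equal(cp$q, exhaustive_q(s5), tolerance = 1e-9)

  set.seed(31)
  for (i in 1:5) {
    m <- random_weighted_graph(7, 0.5)
    if (all(m == 0)) next
    expect_equal(core_periphery(m, n_restart = 8, seed = i)$q,
                 exhaustive_q(m), tolerance = 1e-9)
  }
})

test_that("metrics are invariant to node relabeling", {
  set.seed(41)
  m <- random_weighted_graph(10, 0.6)
  perm <- sample(10)
  mp <- m[perm, perm]
  expect_equal(sort(betweenness_centrality(m)),
               sort(betweenness_centrality(mp)), tolerance = 1e-10)
  expect_equal(shortest_path_metrics(m)$global_efficiency,
               shortest_path_metrics(mp)$global_efficiency, tolerance = 1e-12)
  expect_equal(mean(clustering_and_local_efficiency(m)$clustering),
               mean(clustering_and_local_efficiency(mp)$clustering),
               tolerance = 1e-12)
  expect_equal(k_core_size(m)$size, k_core_size(mp)$size)
  expect_equal(s_core_size(m)$size, s_core_size(mp)$size)
})

test_that("the full suite returns a complete, finite metric row", {
  cfg <- synthetic_cohort_config(n_subjects = 2, ages = c(20, 60), seed = 5)
  coh <- generate_cohort(cfg)
  m <- normalize_weights(
    threshold_to_density(list(coh[[1]]$matrix), 0.1, "fixed")$matrices[[1]])
  suite <- compute_metric_suite(m, n_null = 5, seed = 1)
  expect_equal(nrow(suite$global), 1)
  expect_lt(abs(suite$global$density - 0.1), 1 / 4005)
  num <- vapply(suite$global, is.numeric, logical(1))
  expect_true(all(is.finite(unlist(suite$global[num]))))
  expect_equal(nrow(suite$nodal), 90)
})
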