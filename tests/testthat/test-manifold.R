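# Manifold turning-point machinery: feature matrix, ensemble grid,
# polynomial trajectories, candidate detection/filtering/merging, KDE
# aggregation.

test_that("age feature matrix equals a group-by-mean + z-score oracle", {
  set.seed(3)
  df <- data.frame(age = rep(0:20, each = 3),
                   m1 = rnorm(63), m2 = rnorm(63))
  fm <- build_age_feature_matrix(df)
  # independent oracle
  for (mc in c("m1", "m2")) {
    mu <- tapply(df[[mc]], df$age, mean)
    z <- (mu - mean(mu)) / sd(mu)
    expect_equal(unname(fm[, mc]), as.numeric(z), tolerance = 1e-12)
  }
  expect_true(all(abs(colMeans(fm)) < 1e-9))
  expect_true(all(abs(apply(fm, 2, sd) - 1) < 1e-9))
})

test_that("missing age years are rejected explicitly, constants dropped", {
  df <- data.frame(age = c(0:5, 7:10), m1 = rnorm(10))
  expect_error(build_age_feature_matrix(df), "age\\(s\\): 6")
  df2 <- data.frame(age = rep(0:10, 2), m1 = rnorm(22), m2 = 1)
  expect_warning(fm <- build_age_feature_matrix(df2), "zero-variance")
  expect_equal(colnames(fm), "m1")
})

test_that("two subjects at one rounded age average before standardization", {
  df <- data.frame(age = c(rep(0:29, each = 1), 29.6, 30.4),
                   m1 = c(rnorm(30), 1, 3))
  fm <- build_age_feature_matrix(df)
  mu <- tapply(df$m1, round_half_up(df$age), mean)
  expect_equal(unname(mu[["30"]]), 2)
  expect_equal(unname(fm[31, 1]), unname((mu - mean(mu)) / sd(mu))[[31]])
})

test_that("the default ensemble grid has 968 members, reduced grids multiply", {
  g <- umap_grid()
  expect_equal(nrow(g), 968)
  expect_equal(sort(unique(g$nn)), 2:89)
  expect_equal(length(unique(g$min_dist)), 11)
  expect_equal(range(g$min_dist), c(0.1, 1.0))
  g2 <- umap_grid(nearest_neighbors = c(5, 15), min_dist = c(0.1, 0.5, 1.0))
  expect_equal(nrow(g2), 6)
})

test_that("ensemble embeddings are reproducible and validated", {
  set.seed(1)
  feats <- matrix(rnorm(40 * 4), 40, 4)
  grid <- umap_grid(nearest_neighbors = c(4, 8), min_dist = c(0.2, 0.8),
                    seed = 2)
  e1 <- embed_ensemble(feats, grid)
  e2 <- embed_ensemble(feats, grid)
  expect_equal(length(e1), 4)
  for (i in seq_along(e1)) expect_identical(e1[[i]], e2[[i]])
  expect_equal(ncol(e1[[1]]), 3)
  bad <- umap_grid(nearest_neighbors = 45, min_dist = 0.5)
  expect_error(embed_ensemble(feats, bad), "nearest_neighbors")
})

test_that("polynomial trajectories are exact on polynomial data", {
  ages <- 0:90
  coef <- matrix(c(1, 0.5, -0.01, 2e-4, -1e-6, 5e-9,
                   -2, 0.1, 3e-3, -1e-5, 2e-7, -3e-10,
                   0, -0.3, 2e-3, 1e-5, -3e-7, 1e-9), 6, 3)
  truth <- structure(list(coef = coef, center = 45, degree = 5),
                     class = "polynomial_trajectory")
  emb <- predict_trajectory(truth, ages)
  fit <- fit_trajectory(emb, ages, degree = 5)
  expect_lt(max(abs(fit$coef - coef)), 1e-8)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  # constant dimension: all non-intercept coefficients vanish
  fitc <- fit_trajectory(cbind(rep(2, 91)), ages, degree = 5)
  expect_lt(max(abs(fitc$coef[-1, 1])), 1e-10)

  # noisy data: match an independent normal-equations oracle
  set.seed(8)
  y <- cbind(emb[, 1] + rnorm(91, 0, 0.3))
  fitn <- fit_trajectory(y, ages, degree = 5)
  X <- outer(ages - 45, 0:5, `^`)
  sc <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2, sc, "/")
  oracle <- solve(t(Xs) %*% Xs, t(Xs) %*% y) / sc
  expect_lt(max(abs(fitn$coef - oracle)), 1e-8)

  expect_error(fit_trajectory(cbind(rnorm(4)), c(1, 1, 2, 3), degree = 5),
               "distinct ages")
})

test_that("candidates sit at the derivative's sign flips, refined and rounded", {
  ages <- 0:90
  # parabola with vertex at 30
  emb <- cbind((ages - 30)^2)
  tr <- fit_trajectory(emb, ages, degree = 5)
  expect_equal(detect_candidates(tr, ages), list(30L))

  # strictly monotone: none
  tr2 <- fit_trajectory(cbind(ages^1.0), ages, degree = 5)
  expect_equal(detect_candidates(tr2, ages)[[1]], integer(0))

  # quintic built from derivative roots 10.2 and 55.7 (plus complex pair):
  # p'(x) = (x-10.2)(x-55.7)((x-45)^2+400), integrated analytically
  r1 <- 10.2 - 45; r2 <- 55.7 - 45
  # p'(u) = (u - r1)(u - r2)(u^2 + 400) in centered age u;
  # expand (u - r1)(u - r2) = u^2 - (r1+r2)u + r1 r2
  q <- c(r1 * r2, -(r1 + r2), 1)
  # multiply by (u^2 + 400)
  dcoef <- c(q[1] * 400, q[2] * 400, q[3] * 400 + q[1], q[2], q[3])
  # integrate: coefficient k of p' becomes coefficient k+1 of p, / (k+1)
  pcoef <- c(0, dcoef / seq_along(dcoef))
  tr3 <- structure(list(coef = cbind(pcoef), center = 45, degree = 5),
                   class = "polynomial_trajectory")
  # verify root construction by independent root-finding on the derivative
  roots <- sort(Re(polyroot(dcoef)[abs(Im(polyroot(dcoef))) < 1e-8])) + 45
  expect_equal(roots, c(10.2, 55.7), tolerance = 1e-8)
  expect_equal(detect_candidates(tr3, ages), list(c(10L, 56L)))
})

test_that("gradient filtering applies the windowed-sum cutoff strictly", {
  ages <- 0:90
  # flat trajectory: nothing survives any positive threshold
  expect_equal(filter_candidates(c(10L, 50L), rep(0, 91), ages,
                                 threshold = 0.01), integer(0))

  # windowed sum 0.9 survives at T = 0.8, dies at T = 1.0
  grads <- rep(0, 91)
  grads[26:36] <- 0.9 / 11
  expect_equal(filter_candidates(31L, grads, ages, window = 5,
                                 threshold = 0.8), 31L)
  expect_equal(filter_candidates(31L, grads, ages, window = 5,
                                 threshold = 1.0), integer(0))

  # random quintic fixtures: survivors equal a brute-force recomputation
  set.seed(13)
  for (i in 1:10) {
    coef <- cbind(rnorm(6, sd = c(1, 0.1, 0.01, 1e-3, 1e-5, 1e-7)))
    tr <- structure(list(coef = coef, center = 45, degree = 5),
                    class = "polynomial_trajectory")
    cands <- detect_candidates(tr, ages)[[1]]
    g <- predict_trajectory(tr, ages, deriv = 1)[, 1]
    for (tt in c(0.1, 0.5, 0.8)) {
      got <- filter_candidates(cands, g, ages, window = 5, threshold = tt)
      want <- cands[vapply(cands, function(ci) {
        sum(abs(g[ages >= ci - 5 & ages <= ci + 5])) > tt
      }, logical(1))]
      expect_equal(got, want)
    }
  }
})

test_that("merging chains nearby candidates and averages them", {
  expect_equal(merge_candidates(c(31, 33), 5), 32L)
  expect_equal(merge_candidates(42L, 5), 42L)
  expect_equal(merge_candidates(c(10, 14, 40), 5), c(12L, 40L))
  expect_equal(merge_candidates(integer(0), 5), integer(0))
  # list input pools across dimensions; idempotence
  merged <- merge_candidates(list(c(31L), c(33L), integer(0)), 5)
  expect_equal(merged, 32L)
  expect_equal(merge_candidates(merged, 5), merged)
  # merged ages lie within the span of their members
  set.seed(2)
  for (i in 1:20) {
    x <- sort(sample(0:90, sample(2:8, 1)))
    mg <- merge_candidates(x, 5)
    expect_true(all(mg >= min(x) & mg <= max(x)))
  }
})

test_that("KDE aggregation finds cluster peaks and flags flat pools", {
  one <- aggregate_major_turning_points(rep(30L, 50))
  expect_equal(one$major, 30L)

  set.seed(6)
  pool <- c(round(rnorm(60, 10, 1)), round(rnorm(60, 80, 1)))
  two <- aggregate_major_turning_points(pool)
  expect_equal(sort(two$major), c(10L, 80L))
  expect_equal(sum(two$counts$count), 120)

  unif <- rep(0:90, 3)
  expect_warning(flat <- aggregate_major_turning_points(unif, bandwidth = 10),
                 "prominence")
  expect_equal(length(flat$major), 0)

  expect_error(aggregate_major_turning_points(integer(0)), "empty")
})

test_that("detect-filter-merge recovers polynomial turning ages exactly", {
  # trajectories whose dimensions are polynomials with derivative roots at
  # the planted ages: the chain must return exactly those ages
  ages <- 0:90
  planted <- c(10, 30, 65, 82)
  u <- planted - 45
  dcoef <- 1e-6 * Reduce(function(p, r) {
    c(0, p) - r * c(p, 0)
  }, u, accumulate = FALSE, init = 1)
  # dcoef: coefficients (ascending) of prod (x - u_k), leading term x^4
  pcoef <- c(0, dcoef / seq_along(dcoef))
  tr <- structure(list(coef = cbind(pcoef), center = 45, degree = 5),
                  class = "polynomial_trajectory")
  cand <- detect_candidates(tr, ages)
  g <- predict_trajectory(tr, ages, deriv = 1)[, 1]
  kept <- filter_candidates(cand[[1]], g, ages, window = 5, threshold = 0)
  expect_equal(merge_candidates(kept, 5), as.integer(planted))
})

test_that("major turning points ignore ensemble member order", {
  set.seed(9)
  members <- replicate(20, sample(c(10L, 30L, 65L), 2), simplify = FALSE)
  a1 <- aggregate_major_turning_points(unlist(members))
  a2 <- aggregate_major_turning_points(unlist(rev(members)))
  expect_equal(a1$major, a2$major)
})
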