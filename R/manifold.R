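# Manifold turning-point detection: age-averaged feature matrix, UMAP
# parameter ensemble, per-dimension polynomial trajectories, gradient-based
# inflection filtering, proximity merging, and kernel-density aggregation
# of major turning points across the ensemble.

#' Build the age-averaged feature matrix
#'
#' Averages each metric within integer age bins (nearest rounded year) and
#' z-scores each column, producing the standardized matrix (rows = ages,
#' columns = metrics) that the embedding ensemble consumes. Columns with
#' zero variance after averaging are dropped with a warning. Missing age
#' years are an error, listed explicitly - no silent interpolation.
#'
#' @param metric_table Data.frame with an `age` column and one numeric
#'   column per metric.
#' @param metric_cols Character vector of metric columns (default: all
#'   numeric columns except `age`).
#' @param age_range Integer `c(min, max)` the matrix must cover; default
#'   the observed rounded range.
#' @return A numeric matrix with rownames the integer ages; attribute
#'   `ages` carries them as integers.
#' @export
build_age_feature_matrix <- function(metric_table, metric_cols = NULL,
                                     age_range = NULL) {
  stopifnot(is.data.frame(metric_table), "age" %in% names(metric_table))
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metric_table)[vapply(metric_table, is.numeric,
                                                      logical(1))], "age")
  }
  bins <- round_half_up(metric_table$age)
  if (is.null(age_range)) age_range <- range(bins)
  wanted <- seq(age_range[1], age_range[2])
  missing_years <- setdiff(wanted, unique(bins))
  if (length(missing_years) > 0) {
    stop(sprintf("no subjects at integer age(s): %s",
                 paste(missing_years, collapse = ", ")), call. = FALSE)
  }
  agg <- do.call(rbind, lapply(wanted, function(a) {
    colMeans(metric_table[bins == a, metric_cols, drop = FALSE])
  }))
  sds <- apply(agg, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance metric column(s): %s",
                    paste(metric_cols[sds == 0], collapse = ", ")))
    agg <- agg[, sds > 0, drop = FALSE]
  }
  out <- scale(agg)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  rownames(out) <- wanted
  attr(out, "ages") <- as.integer(wanted)
  out
}

#' Define a UMAP parameter ensemble grid
#'
#' The default grid crosses 88 integer nearest-neighbor values (2 to 89)
#' with 11 evenly spaced minimum distances (0.1 to 1), giving 968 members,
#' each a 3-component Euclidean UMAP. Every member gets a deterministic
#' seed derived from `(nn, min_dist, seed)` so the ensemble is reproducible
#' member by member.
#'
#' @param nearest_neighbors Integer vector (default `2:89`).
#' @param min_dist Numeric vector (default `seq(0.1, 1, length.out = 11)`).
#' @param n_components Embedding dimension (default 3).
#' @param seed Global integer seed.
#' @return Data.frame with one row per member: `nn`, `min_dist`, `seed`.
#' @export
umap_grid <- function(nearest_neighbors = 2:89,
                      min_dist = seq(0.1, 1, length.out = 11),
                      n_components = 3, seed = 1) {
  stopifnot(all(nearest_neighbors >= 2), length(nearest_neighbors) >= 1,
            length(min_dist) >= 1)
  grid <- expand.grid(nn = as.integer(nearest_neighbors),
                      min_dist = min_dist, KEEP.OUT.ATTRS = FALSE)
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) {
    derive_seed(seed, grid$nn[i], round(grid$min_dist[i] * 1000))
  }, integer(1))
  attr(grid, "n_components") <- as.integer(n_components)
  grid
}

#' Embed the feature matrix with every ensemble member
#'
#' Runs one 3-dimensional Euclidean UMAP per grid row. Members whose
#' nearest-neighbor count is not below the number of age rows are rejected
#' at validation time.
#'
#' @param features Matrix from [build_age_feature_matrix()].
#' @param grid Data.frame from [umap_grid()].
#' @return List of embedding matrices (rows = ages, 3 columns), one per
#'   grid member, each with attributes `nn`, `min_dist`, `seed`.
#' @export
embed_ensemble <- function(features, grid) {
  n_row <- nrow(features)
  if (any(grid$nn >= n_row)) {
    stop(sprintf("nearest_neighbors must be < %d (number of age rows); offending members: %s",
                 n_row, paste(which(grid$nn >= n_row), collapse = ", ")),
         call. = FALSE)
  }
  ncomp <- attr(grid, "n_components") %||% 3L
  lapply(seq_len(nrow(grid)), function(i) {
    set.seed(grid$seed[i])
    emb <- uwot::umap(features, n_neighbors = grid$nn[i],
                      min_dist = grid$min_dist[i], n_components = ncomp,
                      metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
                      verbose = FALSE)
    attr(emb, "nn") <- grid$nn[i]
    attr(emb, "min_dist") <- grid$min_dist[i]
    attr(emb, "seed") <- grid$seed[i]
    emb
  })
}

#' Fit per-dimension polynomial trajectories through an embedding
#'
#' Independent least-squares polynomials of age, one per embedding
#' dimension. Internally the fit uses age centered at the midpoint of the
#' age range for numerical conditioning; predictions and derivatives are in
#' original age units.
#'
#' @param embedding Matrix (rows = ages, columns = dimensions).
#' @param ages Numeric ages, one per row.
#' @param degree Polynomial degree (default 5).
#' @return Object of class `polynomial_trajectory`: list with `coef`
#'   (matrix `(degree+1) x ndim` of coefficients in the centered basis),
#'   `center`, `degree`, `ages`, `residuals`.
#' @export
fit_trajectory <- function(embedding, ages, degree = 5) {
  embedding <- as.matrix(embedding)
  stopifnot(nrow(embedding) == length(ages), degree >= 2)
  if (length(unique(ages)) < degree + 1) {
    stop("need at least degree + 1 distinct ages", call. = FALSE)
  }
  center <- mean(range(ages))
  x <- ages - center
  X <- outer(x, 0:degree, `^`)
  qrX <- qr(X)
  if (qrX$rank < degree + 1) stop("rank-deficient polynomial design", call. = FALSE)
  coefs <- qr.coef(qrX, embedding)
  structure(list(coef = coefs, center = center, degree = degree,
                 ages = ages, residuals = embedding - X %*% coefs),
            class = "polynomial_trajectory")
}

#' Evaluate a fitted trajectory
#'
#' @param traj A `polynomial_trajectory`.
#' @param ages Ages at which to evaluate.
#' @param deriv Derivative order (0 = value, 1 = gradient).
#' @return Matrix (length(ages) x ndim).
#' @export
predict_trajectory <- function(traj, ages, deriv = 0) {
  x <- ages - traj$center
  d <- traj$degree
  out <- matrix(0, length(ages), ncol(traj$coef))
  for (k in deriv:d) {
    fac <- prod(seq(k, length.out = deriv, by = -1))
    if (deriv == 0) fac <- 1
    out <- out + outer(x^(k - deriv), traj$coef[k + 1, ]) * fac
  }
  out
}

#' Detect candidate turning ages from a trajectory
#'
#' Evaluates the analytic derivative of each fitted dimension at integer
#' ages; every consecutive sign flip is refined to the real root of the
#' derivative within that one-year interval and rounded to the nearest
#' integer age.
#'
#' @param traj A `polynomial_trajectory`.
#' @param ages Integer ages to scan (default the fitted range).
#' @return List of integer candidate age vectors, one per dimension.
#' @export
detect_candidates <- function(traj, ages = NULL) {
  if (is.null(ages)) {
    ages <- seq(floor(min(traj$ages)), ceiling(max(traj$ages)))
  }
  grads <- predict_trajectory(traj, ages, deriv = 1)
  lapply(seq_len(ncol(grads)), function(dim) {
    g <- grads[, dim]
    if (all(abs(g) < 1e-12)) return(integer(0))
    cands <- integer(0)
    s <- sign(g)
    for (i in seq_len(length(ages) - 1)) {
      if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
        root <- tryCatch(
          stats::uniroot(function(a) predict_trajectory(traj, a, deriv = 1)[1, dim],
                         lower = ages[i], upper = ages[i + 1], tol = 1e-10)$root,
          error = function(e) (ages[i] + ages[i + 1]) / 2)
        cands <- c(cands, round_half_up(root))
      } else if (s[i] != 0 && s[i + 1] == 0) {
        cands <- c(cands, ages[i + 1])
      }
    }
    unique(cands)
  })
}

#' Filter candidate inflections by local gradient mass
#'
#' A candidate at integer age i survives iff the sum of absolute fitted
#' gradients over the window `[i - W, i + W]` (truncated at the age-range
#' boundaries) strictly exceeds the threshold T. This removes minor
#' wobbles of the polynomial fit whose surrounding slopes are small.
#'
#' @param candidates Integer candidate ages (one dimension).
#' @param gradients Named or plain numeric vector of fitted gradients at
#'   the integer ages `grid_ages`.
#' @param grid_ages Integer ages aligned with `gradients`.
#' @param window Gradient window W in years (default 5).
#' @param threshold Gradient threshold T (default 0.8).
#' @return The surviving candidate ages.
#' @export
filter_candidates <- function(candidates, gradients, grid_ages,
                              window = 5, threshold = 0.8) {
  stopifnot(window >= 1, threshold >= 0,
            length(gradients) == length(grid_ages))
  keep <- vapply(candidates, function(i) {
    idx <- which(grid_ages >= i - window & grid_ages <= i + window)
    sum(abs(gradients[idx])) > threshold
  }, logical(1))
  candidates[keep]
}

#' Merge nearby candidates within and across dimensions
#'
#' Single-linkage clustering of all candidate ages with linking distance
#' `age_window`: sorted candidates are chained while consecutive gaps are
#' at most `age_window`, and each chain is replaced by its mean, rounded
#' half-up. Two inflections at 31 and 33 in different dimensions therefore
#' merge to a single turning point at 32.
#'
#' @param candidates Integer vector (all dimensions pooled) or list of
#'   per-dimension vectors.
#' @param age_window Linking distance A in years (default 5).
#' @return Sorted integer turning ages for this embedding.
#' @export
merge_candidates <- function(candidates, age_window = 5) {
  stopifnot(age_window >= 1)
  x <- sort(unlist(candidates))
  if (length(x) == 0) return(integer(0))
  cluster_id <- cumsum(c(1, diff(x) > age_window))
  as.integer(vapply(split(x, cluster_id),
                    function(v) round_half_up(mean(v)), integer(1)))
}

# Peak prominences on a regularly sampled curve, scipy-style: for each
# local maximum, walk out to the nearest higher point on each side and take
# the minimum in between; prominence = height - max(left min, right min).
find_peaks <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1
  if (n >= 2) {
    if (y[1] > y[2]) idx <- c(1L, idx)
    if (y[n] > y[n - 1]) idx <- c(idx, n)
  }
  prom <- vapply(idx, function(i) {
    lmin <- y[i]
    j <- i
    while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
    left_base <- if (j == 1 && y[j] <= y[i]) min(y[1:i]) else lmin
    rmin <- y[i]
    j <- i
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
    right_base <- if (j == n && y[j] <= y[i]) min(y[i:n]) else rmin
    y[i] - max(left_base, right_base)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Aggregate major turning points across the ensemble
#'
#' Pools the per-member turning ages, fits a Gaussian kernel density
#' (Silverman bandwidth by default) and reports the KDE's local maxima on a
#' 0.1-year grid whose prominence exceeds `min_prominence` times the global
#' maximum, rounded to integer years. Per-age identification counts are
#' returned alongside.
#'
#' @param pooled Integer vector of turning ages pooled over all members.
#' @param age_range Integer `c(min, max)` support (default `c(0, 90)`).
#' @param bandwidth KDE bandwidth in years, or `"auto"` (default):
#'   Silverman's rule capped at `max_bandwidth`. Silverman's rule targets
#'   unimodal densities and over-smooths a multimodal pool of turning ages,
#'   so the cap keeps the KDE able to resolve peaks at the same scale at
#'   which merging treats candidates as distinct.
#' @param max_bandwidth Cap applied under `"auto"`, in years; default 2.5,
#'   half the default merging age window.
#' @param min_prominence Minimum peak prominence as a fraction of the KDE
#'   maximum (default 0.05).
#' @return A list with `major` (integer ages), `peak_heights`, `counts`
#'   (data.frame of age and identification count), `density` (grid + kde).
#' @export
aggregate_major_turning_points <- function(pooled, age_range = c(0, 90),
                                           bandwidth = "auto",
                                           max_bandwidth = 2.5,
                                           min_prominence = 0.05) {
  pooled <- unlist(pooled)
  if (length(pooled) == 0) stop("pooled turning-point list is empty", call. = FALSE)
  grid <- seq(age_range[1], age_range[2], by = 0.1)
  bw <- if (identical(bandwidth, "auto")) {
    b <- stats::bw.nrd0(pooled)
    if (!is.finite(b) || b <= 0) 1 else min(b, max_bandwidth)
  } else bandwidth
  # reflect at the domain boundaries so the estimate is unbiased near the
  # ends of the age range (and exactly flat for a uniform pool)
  reflected <- c(pooled, 2 * age_range[1] - pooled, 2 * age_range[2] - pooled)
  kde <- stats::density(reflected, bw = bw, from = age_range[1],
                        to = age_range[2], n = length(grid))
  kde$y <- 3 * kde$y
  pk <- find_peaks(kde$y)
  keep <- pk$prominence > min_prominence * max(kde$y)
  if (!any(keep)) {
    warning("no KDE peak exceeds the prominence threshold; no major turning points")
  }
  major_ages <- round_half_up(kde$x[pk$index[keep]])
  tab <- table(factor(pooled, levels = seq(age_range[1], age_range[2])))
  list(major = unique(as.integer(major_ages)),
       peak_heights = kde$y[pk$index[keep]],
       counts = data.frame(age = as.integer(names(tab)),
                           count = as.integer(tab)),
       density = data.frame(age = kde$x, density = kde$y))
}

#' End-to-end turning-point pipeline
#'
#' Builds the age feature matrix, embeds it with every ensemble member,
#' fits per-dimension polynomial trajectories, detects, filters and merges
#' inflections per member, pools the member turning points and aggregates
#' major turning points by KDE peaks. The full provenance (grid, per-member
#' seeds and candidates) is returned.
#'
#' @param metric_table Data.frame with `age` and metric columns.
#' @param grid UMAP grid from [umap_grid()] (default the 968-member grid).
#' @param degree Polynomial degree (default 5).
#' @param window Gradient window W (default 5).
#' @param threshold Gradient threshold T (default 0.8).
#' @param age_window Merging window A (default 5).
#' @param min_prominence KDE peak prominence fraction (default 0.05).
#' @param metric_cols Optional explicit metric columns.
#' @return A list with `major` (integer turning ages = epoch boundaries),
#'   `aggregate` (full KDE report), `per_member` (turning ages per
#'   embedding), `grid`, `features`.
#' @export
run_turning_point_pipeline <- function(metric_table, grid = NULL, degree = 5,
                                       window = 5, threshold = 0.8,
                                       age_window = 5, min_prominence = 0.05,
                                       metric_cols = NULL) {
  features <- build_age_feature_matrix(metric_table, metric_cols = metric_cols)
  ages <- attr(features, "ages")
  if (is.null(grid)) grid <- umap_grid()
  embeddings <- embed_ensemble(features, grid)
  per_member <- lapply(embeddings, function(emb) {
    traj <- fit_trajectory(emb, ages, degree = degree)
    cand <- detect_candidates(traj, ages)
    grads <- predict_trajectory(traj, ages, deriv = 1)
    kept <- lapply(seq_along(cand), function(d) {
      filter_candidates(cand[[d]], grads[, d], ages,
                        window = window, threshold = threshold)
    })
    merge_candidates(kept, age_window = age_window)
  })
  pooled <- unlist(per_member)
  if (length(pooled) == 0) {
    warning("no ensemble member detected a surviving turning point")
    agg <- list(major = integer(0), peak_heights = numeric(0),
                counts = data.frame(age = integer(0), count = integer(0)),
                density = NULL)
  } else {
    agg <- aggregate_major_turning_points(pooled, age_range = range(ages),
                                          max_bandwidth = age_window / 2,
                                          min_prominence = min_prominence)
  }
  list(major = agg$major, aggregate = agg, per_member = per_member,
       grid = grid, features = features)
}
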