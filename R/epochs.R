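# Epoch characterization: assignment of subjects to lifespan epochs and the
# within/between-epoch statistical suite - Pearson correlations with
# direction-change detection, regional FDR-corrected correlations, LASSO
# age prediction with the one-standard-error rule, PCA with parallel
# analysis and varimax rotation, Levene/Welch/Games-Howell comparisons, and
# dynamic time warping of per-age score trajectories.

#' Assign subjects to epochs
#'
#' Epochs are the half-open age intervals `[b_{k-1}, b_k)` between ordered
#' boundary ages, on the nearest rounded year; the first epoch starts at
#' the age minimum and the last is closed at the maximum. A boundary age
#' itself belongs to the following epoch. An empty boundary list yields a
#' single epoch.
#'
#' @param ages Numeric ages.
#' @param boundaries Strictly increasing boundary ages within `(0, 90)`.
#' @param age_range Allowed age range (default `c(0, 90)`).
#' @return Integer epoch index per subject (1-based), with the boundary
#'   vector in `attr(, "boundaries")`.
#' @export
assign_epochs <- function(ages, boundaries = numeric(0), age_range = c(0, 90)) {
  if (any(ages < age_range[1] | ages > age_range[2])) {
    stop(sprintf("ages must lie within [%g, %g]", age_range[1], age_range[2]),
         call. = FALSE)
  }
  if (length(boundaries) > 0 && any(diff(boundaries) <= 0)) {
    stop("`boundaries` must be strictly increasing", call. = FALSE)
  }
  bins <- round_half_up(ages)
  idx <- findInterval(bins, boundaries) + 1L
  attr(idx, "boundaries") <- boundaries
  idx
}

#' Within-epoch Pearson correlations and direction changes
#'
#' Computes the Pearson correlation of each metric with age inside each
#' epoch, flags significance at `alpha`, and marks direction changes:
#' consecutive epochs in which the metric-age correlation is significant on
#' both sides with opposite signs. Zero-variance metrics within an epoch
#' yield `NA` with a `degenerate` flag rather than being dropped.
#'
#' @param metric_table Data.frame with `age` plus metric columns.
#' @param epochs Integer epoch per row (from [assign_epochs()]).
#' @param metric_cols Metric columns (default all numeric except `age`).
#' @param alpha Significance level (default 0.05, two-sided).
#' @return A list with `correlations` (epoch x metric rows: r, p,
#'   significant, degenerate) and `direction_changes` (metric, from_epoch,
#'   to_epoch).
#' @export
epoch_correlations <- function(metric_table, epochs, metric_cols = NULL,
                               alpha = 0.05) {
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metric_table)[vapply(metric_table, is.numeric,
                                                      logical(1))], "age")
  }
  eps <- sort(unique(epochs))
  rows <- list()
  for (e in eps) {
    sel <- metric_table[epochs == e, , drop = FALSE]
    if (nrow(sel) < 3) stop(sprintf("epoch %d has fewer than 3 subjects", e),
                            call. = FALSE)
    for (mc in metric_cols) {
      if (stats::sd(sel[[mc]]) == 0 || stats::sd(sel$age) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          epoch = e, metric = mc, r = NA_real_, p = NA_real_,
          n = nrow(sel), significant = FALSE, degenerate = TRUE)
      } else {
        ct <- stats::cor.test(sel$age, sel[[mc]])
        rows[[length(rows) + 1]] <- data.frame(
          epoch = e, metric = mc, r = unname(ct$estimate), p = ct$p.value,
          n = nrow(sel), significant = ct$p.value < alpha, degenerate = FALSE)
      }
    }
  }
  corr <- do.call(rbind, rows)
  dc <- list()
  for (mc in metric_cols) {
    sub <- corr[corr$metric == mc, ]
    sub <- sub[order(sub$epoch), ]
    for (i in seq_len(nrow(sub) - 1)) {
      if (isTRUE(sub$significant[i]) && isTRUE(sub$significant[i + 1]) &&
          sign(sub$r[i]) * sign(sub$r[i + 1]) == -1) {
        dc[[length(dc) + 1]] <- data.frame(metric = mc,
                                           from_epoch = sub$epoch[i],
                                           to_epoch = sub$epoch[i + 1])
      }
    }
  }
  list(correlations = corr,
       direction_changes = if (length(dc)) do.call(rbind, dc) else
         data.frame(metric = character(0), from_epoch = integer(0),
                    to_epoch = integer(0)))
}

#' Regional correlations with FDR correction
#'
#' Correlates a nodal metric with age per region within each epoch and
#' applies Benjamini-Hochberg adjustment across the regions of each
#' (epoch, metric) family.
#'
#' @param nodal_table Data.frame with `age`, `node` and metric columns.
#' @param epochs Integer epoch per row.
#' @param metric_cols Metric columns (default all numeric except `age`,
#'   `node`).
#' @param alpha Significance level on adjusted q values (default 0.05).
#' @return Data.frame with epoch, metric, node, r, p, q, significant; the
#'   per-(epoch, metric) significant-region counts in
#'   `attr(, "region_counts")`.
#' @export
regional_correlations <- function(nodal_table, epochs, metric_cols = NULL,
                                  alpha = 0.05) {
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(nodal_table)[vapply(nodal_table, is.numeric,
                                                     logical(1))],
                           c("age", "node"))
  }
  out <- list()
  for (e in sort(unique(epochs))) {
    sel <- nodal_table[epochs == e, , drop = FALSE]
    for (mc in metric_cols) {
      nodes <- sort(unique(sel$node))
      r <- p <- rep(NA_real_, length(nodes))
      for (k in seq_along(nodes)) {
        sn <- sel[sel$node == nodes[k], ]
        if (nrow(sn) >= 3 && stats::sd(sn[[mc]]) > 0) {
          ct <- stats::cor.test(sn$age, sn[[mc]])
          r[k] <- unname(ct$estimate); p[k] <- ct$p.value
        }
      }
      q <- stats::p.adjust(p, method = "BH")
      out[[length(out) + 1]] <- data.frame(epoch = e, metric = mc,
                                           node = nodes, r = r, p = p, q = q,
                                           significant = !is.na(q) & q < alpha)
    }
  }
  res <- do.call(rbind, out)
  counts <- stats::aggregate(significant ~ epoch + metric, data = res, FUN = sum)
  attr(res, "region_counts") <- counts
  res
}

#' LASSO age prediction within epochs
#'
#' Fits a cross-validated LASSO of age on the (within-epoch standardized)
#' metrics for each epoch. The penalty is chosen by the one-standard-error
#' rule - the largest lambda whose CV mean squared error is within one SE
#' of the minimum. If that model retains no predictors, the minimum-MSE
#' lambda is used instead and the epoch is flagged (`rule = "min-MSE"`),
#' mirroring the need to weaken regularization in data-poor epochs.
#'
#' @param metric_table Data.frame with `age` plus metric columns.
#' @param epochs Integer epoch per row.
#' @param metric_cols Metric columns (default all numeric except `age`).
#' @param folds CV folds (default 10).
#' @param seed Integer seed (fold assignment).
#' @return A list per epoch: `beta` (named coefficient vector, intercept
#'   excluded), `lambda`, `rule` (`"one-SE"` or `"min-MSE"`),
#'   `lambda_min`, `lambda_1se`, `n`.
#' @export
lasso_age_prediction <- function(metric_table, epochs, metric_cols = NULL,
                                 folds = 10, seed = 1) {
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metric_table)[vapply(metric_table, is.numeric,
                                                      logical(1))], "age")
  }
  out <- list()
  for (e in sort(unique(epochs))) {
    sel <- metric_table[epochs == e, , drop = FALSE]
    if (nrow(sel) <= folds) {
      stop(sprintf("epoch %d has n = %d <= %d folds", e, nrow(sel), folds),
           call. = FALSE)
    }
    y <- sel$age
    if (stats::sd(y) == 0) stop(sprintf("epoch %d has constant age", e),
                                call. = FALSE)
    x <- as.matrix(sel[, metric_cols, drop = FALSE])
    keep <- apply(x, 2, stats::sd) > 0
    xs <- scale(x[, keep, drop = FALSE])
    set.seed(derive_seed(seed, 131L, e))
    cv <- glmnet::cv.glmnet(xs, y, alpha = 1, nfolds = folds,
                            standardize = FALSE)
    pick <- function(lam) {
      b <- as.numeric(stats::coef(cv, s = lam))[-1]
      names(b) <- colnames(xs)
      b
    }
    beta <- pick(cv$lambda.1se)
    rule <- "one-SE"
    lambda <- cv$lambda.1se
    if (all(beta == 0)) {
      beta <- pick(cv$lambda.min)
      rule <- "min-MSE"
      lambda <- cv$lambda.min
    }
    full_beta <- stats::setNames(rep(0, length(metric_cols)), metric_cols)
    full_beta[names(beta)] <- beta
    out[[as.character(e)]] <- list(beta = full_beta, lambda = lambda,
                                   rule = rule, lambda_min = cv$lambda.min,
                                   lambda_1se = cv$lambda.1se, n = nrow(sel))
  }
  out
}

#' PCA with parallel analysis and varimax rotation
#'
#' Standardizes the metrics, takes the eigenvalues of their correlation
#' matrix, and retains the leading components whose eigenvalues exceed the
#' chosen percentile (default 95th) of eigenvalues from `n_iter` random
#' standard-normal datasets of the same shape (parallel analysis). The
#' retained loadings are varimax-rotated (Kaiser normalization) and
#' per-subject rotated scores returned.
#'
#' @param metric_table Data.frame with metric columns (an `age` column, if
#'   present, is ignored as a predictor).
#' @param metric_cols Metric columns (default all numeric except `age`).
#' @param n_iter Parallel-analysis iterations (default 1000).
#' @param percentile Percentile of random eigenvalues (default 95).
#' @param seed Integer seed.
#' @return A list: `n_retained`, `eigenvalues`, `thresholds` (random
#'   eigenvalue percentiles), `loadings` (rotated, p x k), `scores`
#'   (n x k rotated scores), `variance_explained` (per rotated component,
#'   fraction of total variance), `communalities`.
#' @export
pca_parallel_varimax <- function(metric_table, metric_cols = NULL,
                                 n_iter = 1000, percentile = 95, seed = 1) {
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metric_table)[vapply(metric_table, is.numeric,
                                                      logical(1))], "age")
  }
  x <- as.matrix(metric_table[, metric_cols, drop = FALSE])
  n <- nrow(x); p <- ncol(x)
  if (n < p + 1) stop("need more subjects than metrics", call. = FALSE)
  xs <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  set.seed(derive_seed(seed, 151L))
  rand_eigs <- matrix(0, n_iter, p)
  for (b in seq_len(n_iter)) {
    r <- matrix(stats::rnorm(n * p), n, p)
    rand_eigs[b, ] <- eigen(stats::cor(r), symmetric = TRUE,
                            only.values = TRUE)$values
  }
  thresholds <- apply(rand_eigs, 2, stats::quantile, probs = percentile / 100)
  exceed <- eg$values > thresholds
  k <- if (exceed[1]) which.min(c(exceed, FALSE)) - 1L else 0L
  if (k == 0) {
    warning("parallel analysis retained 0 components")
    return(list(n_retained = 0L, eigenvalues = eg$values,
                thresholds = thresholds, loadings = NULL, scores = NULL,
                variance_explained = numeric(0), communalities = NULL))
  }
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  rownames(L) <- metric_cols
  if (k >= 2) {
    vm <- stats::varimax(L, normalize = TRUE)
    rot <- vm$rotmat
    L_rot <- L %*% rot
  } else {
    rot <- diag(1)
    L_rot <- L
  }
  # unrotated standardized scores, then the same rotation
  scores_un <- xs %*% eg$vectors[, seq_len(k), drop = FALSE]
  scores <- scores_un %*% rot
  colnames(scores) <- colnames(L_rot) <- paste0("PC", seq_len(k))
  list(n_retained = k, eigenvalues = eg$values, thresholds = thresholds,
       loadings = L_rot, scores = scores,
       variance_explained = colSums(L_rot^2) / p,
       communalities = rowSums(L_rot^2))
}

# Games-Howell pairwise test: Welch t statistic referred to the
# studentized-range distribution with Welch-Satterthwaite df.
games_howell_pair <- function(x1, x2, n_groups) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- stats::var(x1) / n1; v2 <- stats::var(x2) / n2
  se <- sqrt(v1 + v2)
  t <- (mean(x1) - mean(x2)) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- stats::ptukey(abs(t) * sqrt(2), nmeans = n_groups, df = df,
                     lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Compare PCA scores across epochs
#'
#' Per principal component: Levene's test (median-centered, via
#' `car::leveneTest`) for variance differences, Welch's one-way ANOVA for
#' mean differences, and post hoc Games-Howell tests for each consecutive
#' epoch pair.
#'
#' @param scores Matrix or data.frame of per-subject component scores.
#' @param epochs Integer epoch per row.
#' @return A list with `levene` (per PC: F, df, p), `welch` (per PC: F,
#'   df1, df2, p), `games_howell` (per PC x consecutive pair: t, df, p)
#'   and `group_stats` (per epoch x PC mean/SD/variance/n).
#' @export
compare_epoch_scores <- function(scores, epochs) {
  scores <- as.matrix(scores)
  eps <- sort(unique(epochs))
  if (length(eps) < 2) stop("need at least 2 epochs", call. = FALSE)
  ns <- table(factor(epochs, levels = eps))
  if (any(ns < 3)) stop("every epoch needs at least 3 subjects", call. = FALSE)
  pcs <- colnames(scores)
  if (is.null(pcs)) pcs <- paste0("PC", seq_len(ncol(scores)))
  lev <- wel <- gh <- gstats <- list()
  f_ep <- factor(epochs, levels = eps)
  for (j in seq_len(ncol(scores))) {
    y <- scores[, j]
    lt <- car::leveneTest(y ~ f_ep, center = stats::median)
    lev[[j]] <- data.frame(pc = pcs[j], F = lt$`F value`[1],
                           df1 = lt$Df[1], df2 = lt$Df[2],
                           p = lt$`Pr(>F)`[1])
    wt <- stats::oneway.test(y ~ f_ep, var.equal = FALSE)
    wel[[j]] <- data.frame(pc = pcs[j], F = unname(wt$statistic),
                           df1 = unname(wt$parameter[1]),
                           df2 = unname(wt$parameter[2]),
                           p = wt$p.value)
    for (i in seq_len(length(eps) - 1)) {
      x1 <- y[epochs == eps[i]]; x2 <- y[epochs == eps[i + 1]]
      if (stats::var(x1) == 0 || stats::var(x2) == 0) {
        warning(sprintf("zero within-group variance (PC %s, epochs %d-%d); pair skipped",
                        pcs[j], eps[i], eps[i + 1]))
        next
      }
      g <- games_howell_pair(x1, x2, n_groups = length(eps))
      gh[[length(gh) + 1]] <- data.frame(pc = pcs[j], epoch_a = eps[i],
                                         epoch_b = eps[i + 1], t = g$t,
                                         df = g$df, p = g$p)
    }
    for (e in eps) {
      ye <- y[epochs == e]
      gstats[[length(gstats) + 1]] <- data.frame(
        pc = pcs[j], epoch = e, n = length(ye), mean = mean(ye),
        sd = stats::sd(ye), variance = stats::var(ye))
    }
  }
  list(levene = do.call(rbind, lev), welch = do.call(rbind, wel),
       games_howell = do.call(rbind, gh),
       group_stats = do.call(rbind, gstats))
}

#' Dynamic time warping distance
#'
#' Classic full-window DTW between two univariate series with Euclidean
#' (absolute-difference) local cost: the minimum cumulative cost of a
#' monotone alignment path allowing steps right, down and diagonal.
#'
#' @param a,b Numeric series of length `>= 2`.
#' @return The DTW distance (0 for identical series).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both series must have length >= 2", call. = FALSE)
  }
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- abs(a[i] - b[j])
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

#' DTW comparison of epoch score trajectories
#'
#' Builds, for each epoch and component, the series of mean scores per
#' integer age, computes the DTW distance between each consecutive epoch
#' pair, z-scores the raw distances within each component across the pair
#' set, and sums the standardized distances over components per pair.
#'
#' @param scores Matrix of per-subject component scores.
#' @param epochs Integer epoch per subject.
#' @param ages Numeric age per subject.
#' @return A list with `distances` (pc, epoch_a, epoch_b, raw, z) and
#'   `pair_sums` (epoch pair, summed standardized distance).
#' @export
dtw_epoch_trajectories <- function(scores, epochs, ages) {
  scores <- as.matrix(scores)
  eps <- sort(unique(epochs))
  if (length(eps) < 2) stop("need at least 2 epochs", call. = FALSE)
  pcs <- colnames(scores)
  if (is.null(pcs)) pcs <- paste0("PC", seq_len(ncol(scores)))
  bins <- round_half_up(ages)
  series <- lapply(eps, function(e) {
    sel <- which(epochs == e)
    ag <- sort(unique(bins[sel]))
    if (length(ag) < 3) stop(sprintf("epoch %d spans fewer than 3 ages", e),
                             call. = FALSE)
    sapply(seq_len(ncol(scores)), function(j) {
      vapply(ag, function(a) mean(scores[sel[bins[sel] == a], j]), numeric(1))
    })
  })
  rows <- list()
  for (j in seq_len(ncol(scores))) {
    for (i in seq_len(length(eps) - 1)) {
      raw <- dtw_distance(series[[i]][, j], series[[i + 1]][, j])
      rows[[length(rows) + 1]] <- data.frame(pc = pcs[j], epoch_a = eps[i],
                                             epoch_b = eps[i + 1], raw = raw)
    }
  }
  d <- do.call(rbind, rows)
  d$z <- stats::ave(d$raw, d$pc, FUN = function(v) {
    if (stats::sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / stats::sd(v)
  })
  pair_sums <- stats::aggregate(z ~ epoch_a + epoch_b, data = d, FUN = sum)
  names(pair_sums)[3] <- "summed_z"
  list(distances = d, pair_sums = pair_sums)
}
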