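# Preprocessing: density computation, per-age-bin outlier removal,
# harmonization mask post-processing, density-targeted thresholding
# (variable and fixed modes) and weight normalization, plus the generic
# age smoother used for density targets and peak/valley detection.

#' Network density
#'
#' Fraction of possible node pairs connected by a nonzero edge.
#'
#' @param m Connectivity matrix.
#' @return Density in `[0, 1]`.
#' @export
compute_density <- function(m) {
  check_connectivity_matrix(m)
  n <- nrow(m)
  sum(m[upper.tri(m)] > 0) / (n * (n - 1) / 2)
}

#' Remove per-age-bin density outliers
#'
#' Subjects whose network density lies more than `n_sd` standard deviations
#' from the mean of their age bin (nearest rounded year) are removed. Bins
#' with fewer than two subjects, or zero density SD, are passed through
#' untouched.
#'
#' @param cohort List of subject records (each with `age` and `matrix`).
#' @param n_sd Outlier cutoff in SD units (default 3).
#' @return A list with `kept` (the filtered cohort), `removed_ids` and a
#'   `log` data.frame (subject, bin, density, bin mean/SD, removed flag).
#' @export
remove_density_outliers <- function(cohort, n_sd = 3) {
  dens <- vapply(cohort, function(s) compute_density(s$matrix), numeric(1))
  bins <- round_half_up(vapply(cohort, function(s) s$age, numeric(1)))
  removed <- logical(length(cohort))
  bin_mean <- bin_sd <- rep(NA_real_, length(cohort))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) next
    mu <- mean(dens[idx]); sdv <- stats::sd(dens[idx])
    bin_mean[idx] <- mu; bin_sd[idx] <- sdv
    if (sdv == 0) next
    removed[idx] <- abs(dens[idx] - mu) > n_sd * sdv
  }
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  list(kept = cohort[!removed],
       removed_ids = ids[removed],
       log = data.frame(subject_id = ids, age_bin = bins, density = dens,
                        bin_mean = bin_mean, bin_sd = bin_sd,
                        removed = removed, stringsAsFactors = FALSE))
}

#' Post-process a harmonized matrix against its original
#'
#' Batch harmonization (e.g. ComBat, run externally) can create connections
#' where none existed and negative weights. This mask retains only
#' connections present before harmonization and clips negative harmonized
#' weights to zero; all other entries pass through unchanged.
#'
#' @param harmonized,original Connectivity matrices of identical shape.
#' @return The masked, clipped harmonized matrix.
#' @export
apply_harmonization_mask <- function(harmonized, original) {
  if (!identical(dim(harmonized), dim(original))) {
    stop("`harmonized` and `original` must have the same shape", call. = FALSE)
  }
  out <- harmonized
  out[original == 0] <- 0
  out[out < 0] <- 0
  out
}

#' Fit a smooth age trend and locate derivative sign switches
#'
#' Fits a cross-validated cubic smoothing spline of `y` on age and reports
#' fitted values, the fitted derivative at integer ages, and the ages at
#' which the derivative changes sign (peaks and valleys of the trend). Each
#' sign switch is localized by linear interpolation of the derivative
#' between adjacent integer ages and rounded to the nearest year.
#'
#' @param ages Numeric ages.
#' @param y Values to smooth.
#' @param grid_ages Integer ages at which to evaluate (default the integer
#'   range of `ages`).
#' @return A list with `grid_ages`, `fitted`, `derivative`, `sign_switches`
#'   (integer ages) and `constant` (TRUE when `y` has zero variance, in
#'   which case the switch list is empty).
#' @export
fit_age_smoother <- function(ages, y, grid_ages = NULL) {
  if (length(unique(ages)) < 10) {
    stop("need at least 10 distinct ages to fit the age smoother", call. = FALSE)
  }
  if (is.null(grid_ages)) {
    grid_ages <- seq(floor(min(ages)), ceiling(max(ages)))
  }
  if (stats::var(y) == 0) {
    return(list(grid_ages = grid_ages,
                fitted = rep(y[1], length(grid_ages)),
                derivative = rep(0, length(grid_ages)),
                sign_switches = integer(0), constant = TRUE))
  }
  fit <- stats::smooth.spline(ages, y, cv = FALSE)
  fitted <- stats::predict(fit, grid_ages)$y
  deriv <- stats::predict(fit, grid_ages, deriv = 1)$y
  sw <- integer(0)
  s <- sign(deriv)
  for (i in seq_len(length(grid_ages) - 1)) {
    if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
      # linear zero crossing between the two grid ages
      a <- grid_ages[i] + deriv[i] / (deriv[i] - deriv[i + 1])
      sw <- c(sw, round_half_up(a))
    } else if (s[i] != 0 && s[i + 1] == 0) {
      sw <- c(sw, grid_ages[i + 1])
    }
  }
  list(grid_ages = grid_ages, fitted = fitted, derivative = deriv,
       sign_switches = unique(sw), constant = FALSE)
}

#' Variable-density thresholding targets
#'
#' Smooths raw network density over age and takes 70% of the fitted trend
#' as the target density for each integer age, preserving the lifespan
#' density profile while removing the weakest edges.
#'
#' @param cohort List of subject records.
#' @param fraction Fraction of the fitted trend used as target (default 0.7).
#' @return A data.frame with `age` and `target` columns (class
#'   `density_target_curve`).
#' @export
compute_variable_density_targets <- function(cohort, fraction = 0.7) {
  ages <- vapply(cohort, function(s) s$age, numeric(1))
  dens <- vapply(cohort, function(s) compute_density(s$matrix), numeric(1))
  sm <- fit_age_smoother(ages, dens)
  target <- fraction * sm$fitted
  if (any(target <= 0)) {
    stop("variable-density targets must be positive; smoothed density dips to zero",
         call. = FALSE)
  }
  out <- data.frame(age = sm$grid_ages, target = target)
  class(out) <- c("density_target_curve", class(out))
  out
}

# Threshold one matrix to keep exactly the k strongest edges; ties at the
# cutoff weight are admitted in descending weight order, stable by
# upper-triangle node-pair index.
keep_top_k_edges <- function(m, k) {
  n <- nrow(m)
  w <- m[upper.tri(m)]
  pos <- which(w > 0)
  if (k >= length(pos)) return(m)
  ord <- pos[order(-w[pos], seq_along(pos))]  # weight desc, pair index asc
  drop <- ord[-seq_len(k)]
  keep_mask <- rep(TRUE, length(w))
  keep_mask[drop] <- FALSE
  w[!keep_mask] <- 0
  out <- matrix(0, n, n)
  out[upper.tri(out)] <- w
  out + t(out)
}

#' Threshold networks to a target density
#'
#' Two modes. In `"fixed"` mode each matrix is independently thresholded so
#' its own density equals `target` as closely as ties permit: the target
#' edge count is `round(target * n(n-1)/2)` and the strongest edges are
#' kept, ties at the cutoff admitted in a deterministic node-pair order. In
#' `"variable"` mode a single absolute weight cutoff is chosen for the whole
#' group (by brute force over the sorted set of observed weights) so that
#' the group's mean post-threshold density is closest to `target`; edges
#' strictly below the cutoff are zeroed in every matrix.
#'
#' @param group List of connectivity matrices.
#' @param target Target density in `(0, 1]`.
#' @param mode `"fixed"` or `"variable"`.
#' @return A list with `matrices`, `cutoff` (the weight cutoff; per-matrix
#'   vector in fixed mode) and `achieved` (per-matrix densities).
#' @export
threshold_to_density <- function(group, target, mode = c("fixed", "variable")) {
  mode <- match.arg(mode)
  stopifnot(length(group) >= 1)
  if (target <= 0 || target > 1) stop("`target` must be in (0, 1]", call. = FALSE)
  for (m in group) check_connectivity_matrix(m)
  raw_d <- vapply(group, compute_density, numeric(1))
  if (mode == "fixed") {
    out <- vector("list", length(group))
    cutoffs <- numeric(length(group))
    for (i in seq_along(group)) {
      m <- group[[i]]
      n <- nrow(m)
      npairs <- n * (n - 1) / 2
      k <- round(target * npairs)
      if (raw_d[i] <= target) {
        if (raw_d[i] < target) {
          warning(sprintf("matrix %d raw density %.3f below target %.3f; left unthresholded",
                          i, raw_d[i], target))
        }
        out[[i]] <- m
        cutoffs[i] <- 0
      } else {
        out[[i]] <- keep_top_k_edges(m, k)
        kept <- out[[i]][upper.tri(out[[i]])]
        cutoffs[i] <- min(kept[kept > 0])
      }
    }
    return(list(matrices = out, cutoff = cutoffs,
                achieved = vapply(out, compute_density, numeric(1))))
  }
  # variable mode: one absolute cutoff for the whole group
  all_w <- sort(unique(unlist(lapply(group, function(m) {
    w <- m[upper.tri(m)]; w[w > 0]
  }))))
  if (mean(raw_d) <= target) {
    if (mean(raw_d) < target) {
      warning(sprintf("group mean density %.3f below target %.3f; returned unthresholded",
                      mean(raw_d), target))
    }
    return(list(matrices = group, cutoff = 0, achieved = raw_d))
  }
  candidates <- c(0, all_w)
  npairs <- vapply(group, function(m) nrow(m) * (nrow(m) - 1) / 2, numeric(1))
  best <- NULL
  for (cut in candidates) {
    dens <- vapply(seq_along(group), function(i) {
      w <- group[[i]][upper.tri(group[[i]])]
      sum(w >= cut & w > 0) / npairs[i]
    }, numeric(1))
    err <- abs(mean(dens) - target)
    if (is.null(best) || err < best$err - 1e-15) {
      best <- list(cut = cut, err = err)
    }
  }
  mats <- lapply(group, function(m) { m[m < best$cut] <- 0; m })
  list(matrices = mats, cutoff = best$cut,
       achieved = vapply(mats, compute_density, numeric(1)))
}

#' Threshold a cohort with age-varying density targets
#'
#' Applies [threshold_to_density()] in variable mode within each
#' (integer age bin x dataset) group, using the group's age-specific target
#' from a [compute_variable_density_targets()] curve.
#'
#' @param cohort List of subject records.
#' @param targets A `density_target_curve`.
#' @return The cohort with thresholded matrices; per-group cutoffs in
#'   `attr(, "cutoffs")`.
#' @export
threshold_cohort_variable <- function(cohort, targets) {
  bins <- round_half_up(vapply(cohort, function(s) s$age, numeric(1)))
  dsets <- vapply(cohort, function(s) s$dataset, character(1))
  key <- paste(bins, dsets, sep = "|")
  cutlog <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    age <- bins[idx[1]]
    tgt <- targets$target[match(age, targets$age)]
    if (is.na(tgt)) stop(sprintf("no density target for age %d", age), call. = FALSE)
    th <- threshold_to_density(lapply(cohort[idx], `[[`, "matrix"),
                               tgt, mode = "variable")
    for (j in seq_along(idx)) cohort[[idx[j]]]$matrix <- th$matrices[[j]]
    cutlog[[k]] <- th$cutoff
  }
  attr(cohort, "cutoffs") <- cutlog
  cohort
}

#' Rescale weights to the unit interval
#'
#' Divides every weight by the matrix maximum so weights range from 0 to 1,
#' the normalization applied before all weighted metric computation.
#'
#' @param m Connectivity matrix with at least one positive weight.
#' @return The normalized matrix (max weight exactly 1).
#' @export
normalize_weights <- function(m) {
  check_connectivity_matrix(m)
  mx <- max(m)
  if (mx == 0) stop("cannot normalize an all-zero matrix", call. = FALSE)
  m / mx
}
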