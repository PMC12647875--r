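# Synthetic cohorts: planted metric trajectories, stochastic-block-model
# streamline-count matrices, and small canonical fixture graphs. These stand
# in for restricted imaging data so the whole pipeline is testable offline.

#' Specify planted metric trajectories
#'
#' Defines a set of per-metric mean curves over age that are piecewise linear
#' with slope changes ("turning points") at known ages, observed with i.i.d.
#' Gaussian noise. Downstream turning-point detection can then be scored
#' against the planted ground truth.
#'
#' By default every metric reverses direction at each turning age (slopes of
#' alternating sign), emulating cohorts in which each lifespan epoch has a
#' distinct direction of topological change. Slope magnitudes are drawn once
#' per metric from `[0.5, 1.5]` using `seed`, so the spec itself is
#' deterministic.
#'
#' @param metric_names Character vector of metric labels.
#' @param turning_ages Strictly increasing integer ages in `(0, 90)` where
#'   slopes change. May be empty.
#' @param segment_slopes Optional numeric matrix (`length(metric_names)` x
#'   `length(turning_ages) + 1`) of per-metric per-segment slopes. If `NULL`,
#'   alternating-sign slopes are drawn as described above.
#' @param noise_sd Nonnegative observation noise SD.
#' @param n_per_age Positive number of subjects at each integer age.
#' @param seed Integer seed.
#' @param age_range Integer vector `c(min, max)`, default `c(0, 90)`.
#' @return An object of class `planted_trajectory_spec`.
#' @export
planted_trajectory_spec <- function(metric_names,
                                    turning_ages = integer(0),
                                    segment_slopes = NULL,
                                    noise_sd = 0.3,
                                    n_per_age = 20,
                                    seed = 1,
                                    age_range = c(0, 90)) {
  stopifnot(length(metric_names) >= 1, is.character(metric_names))
  turning_ages <- as.numeric(turning_ages)
  if (length(turning_ages) > 0) {
    if (any(diff(turning_ages) <= 0)) {
      stop("`turning_ages` must be strictly increasing", call. = FALSE)
    }
    if (any(turning_ages <= age_range[1]) || any(turning_ages >= age_range[2])) {
      stop(sprintf("`turning_ages` must lie strictly inside [%d, %d]",
                   age_range[1], age_range[2]), call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_per_age < 1) stop("`n_per_age` must be >= 1", call. = FALSE)
  n_seg <- length(turning_ages) + 1L
  n_met <- length(metric_names)
  if (is.null(segment_slopes)) {
    set.seed(derive_seed(seed, 11L))
    mag <- matrix(stats::runif(n_met * n_seg, 0.5, 1.5), n_met, n_seg)
    start_sign <- ifelse(stats::runif(n_met) < 0.5, -1, 1)
    sign_pat <- t(vapply(start_sign,
                         function(s) s * (-1)^(seq_len(n_seg) - 1),
                         numeric(n_seg)))
    if (n_seg == 1L) sign_pat <- matrix(start_sign, n_met, 1)
    segment_slopes <- mag * sign_pat
  }
  segment_slopes <- matrix(as.numeric(segment_slopes), n_met, n_seg)
  structure(list(metric_names = metric_names,
                 turning_ages = turning_ages,
                 segment_slopes = segment_slopes,
                 noise_sd = noise_sd,
                 n_per_age = as.integer(n_per_age),
                 seed = as.integer(seed),
                 age_range = as.integer(age_range)),
            class = "planted_trajectory_spec")
}

# Evaluate the continuous piecewise-linear mean curve of one metric.
piecewise_linear_curve <- function(ages, turning_ages, slopes, age0 = 0) {
  knots <- c(age0, turning_ages)
  # value at the start of each segment (curve starts at 0)
  seg_start_val <- c(0, cumsum(slopes[-length(slopes)] * diff(c(knots, NA))[seq_along(turning_ages)]))
  seg <- findInterval(ages, knots)  # segment index, 1-based
  seg_start_val[seg] + slopes[seg] * (ages - knots[seg])
}

#' Generate planted metric trajectories
#'
#' Draws the subject-level metric table implied by a
#' [planted_trajectory_spec()]: `n_per_age` subjects at every integer age,
#' each metric equal to its piecewise-linear mean curve plus Gaussian noise.
#'
#' @param spec A `planted_trajectory_spec`.
#' @return A list with `data` (data.frame: `subject_id`, `age`, one column
#'   per metric) and `turning_ages` (the planted ground truth).
#' @export
generate_metric_trajectories <- function(spec) {
  stopifnot(inherits(spec, "planted_trajectory_spec"))
  ages <- seq(spec$age_range[1], spec$age_range[2])
  all_ages <- rep(ages, each = spec$n_per_age)
  n <- length(all_ages)
  set.seed(derive_seed(spec$seed, 23L))
  out <- data.frame(subject_id = sprintf("sim%05d", seq_len(n)),
                    age = all_ages,
                    stringsAsFactors = FALSE)
  for (j in seq_along(spec$metric_names)) {
    mu <- piecewise_linear_curve(all_ages, spec$turning_ages,
                                 spec$segment_slopes[j, ],
                                 age0 = spec$age_range[1])
    out[[spec$metric_names[j]]] <- mu + stats::rnorm(n, 0, spec$noise_sd)
  }
  list(data = out, turning_ages = spec$turning_ages)
}

#' Configure a synthetic connectome cohort
#'
#' @param n_nodes Number of nodes (default 90, the AAL90 parcellation size).
#' @param n_subjects Number of subjects.
#' @param block_count Number of stochastic-block-model communities.
#' @param density_curve Function mapping age (years) to target density in
#'   `(0, 1]`, or a single number used at every age. The default falls from
#'   0.25 around birth to 0.12 in late life, emulating dense weak networks
#'   early and sparse strong networks late.
#' @param mean_count Baseline Poisson mean for streamline counts of present
#'   edges; the realized mean grows linearly with age so that strength
#'   increases across the lifespan.
#' @param age_range Integer `c(min, max)` ages, default `c(0, 90)`.
#' @param ages Optional explicit integer age per subject (length
#'   `n_subjects`); by default ages are sampled uniformly over the integers
#'   of `age_range` so every age bin is covered in expectation.
#' @param seed Integer seed.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_nodes = 90,
                                    n_subjects = 100,
                                    block_count = 4,
                                    density_curve = NULL,
                                    mean_count = 8,
                                    age_range = c(0, 90),
                                    ages = NULL,
                                    seed = 1) {
  if (n_nodes < 3) stop("`n_nodes` must be >= 3", call. = FALSE)
  if (is.null(density_curve)) {
    density_curve <- function(age) 0.25 - 0.13 * age / 90
  } else if (is.numeric(density_curve) && length(density_curve) == 1) {
    d0 <- density_curve
    density_curve <- function(age) rep(d0, length(age))
  }
  dd <- density_curve(seq(age_range[1], age_range[2]))
  if (any(dd <= 0) || any(dd > 1)) {
    stop("`density_curve` must map every age into (0, 1]", call. = FALSE)
  }
  if (!is.null(ages)) {
    stopifnot(length(ages) == n_subjects)
    if (any(ages < age_range[1] | ages > age_range[2])) {
      stop("explicit `ages` must lie within `age_range`", call. = FALSE)
    }
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_subjects = as.integer(n_subjects),
                 block_count = as.integer(block_count),
                 density_curve = density_curve,
                 mean_count = mean_count,
                 age_range = as.integer(age_range),
                 ages = if (is.null(ages)) NULL else as.integer(ages),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic connectome cohort
#'
#' Draws one stochastic-block-model streamline-count matrix per subject.
#' Edge presence is Bernoulli with within-block probability three times the
#' between-block probability (the ratio drifts upward with age so modularity
#' moves across the lifespan), scaled so the expected density matches the
#' config's `density_curve` at the subject's age. Counts of present edges
#' are `1 + Poisson(lambda)` with `lambda` growing linearly in age, giving
#' integer, right-skewed counts whose strength increases across life.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list of subject records, each a list with `subject_id`, `age`,
#'   `sex`, `dataset`, `atlas` and `matrix` (a symmetric count matrix with
#'   zero diagonal).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_nodes
  set.seed(derive_seed(config$seed, 37L))
  ages <- config$ages
  if (is.null(ages)) {
    ages <- sample(seq(config$age_range[1], config$age_range[2]),
                   config$n_subjects, replace = TRUE)
  }
  sexes <- sample(c("F", "M"), config$n_subjects, replace = TRUE)
  blocks <- sort(rep_len(seq_len(config$block_count), n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same_block <- blocks[ut[, 1]] == blocks[ut[, 2]]
  f_within <- mean(same_block)
  lapply(seq_len(config$n_subjects), function(i) {
    age <- ages[i]
    d_target <- config$density_curve(age)
    ratio <- 2 + age / 45            # within:between contrast grows with age
    p_between <- d_target / (f_within * ratio + (1 - f_within))
    p_within <- min(1, ratio * p_between)
    p_edge <- ifelse(same_block, p_within, p_between)
    present <- stats::rbinom(nrow(ut), 1, p_edge) == 1
    lambda <- config$mean_count * (0.5 + 1.5 * age / 90)
    counts <- numeric(nrow(ut))
    counts[present] <- 1 + stats::rpois(sum(present), lambda)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- counts
    m <- m + t(m)
    list(subject_id = sprintf("syn%05d", i),
         age = age, sex = sexes[i], dataset = "synthetic",
         atlas = "AAL90", matrix = m)
  })
}

#' Generate a canonical toy network
#'
#' Small fixture graphs with known metric values, used as oracles for the
#' graph-metric suite.
#'
#' @param kind One of `"complete"`, `"ring"`, `"star"`, `"path"`,
#'   `"two_cliques"`, `"sbm"`.
#' @param size Number of nodes (`>= 2`; even for `two_cliques`).
#' @param weight Edge weight used for every edge (default 1).
#' @param ... For `kind = "sbm"`: `block_count`, `p_within`, `p_between`,
#'   `seed`.
#' @return A connectivity matrix.
#' @export
generate_toy_network <- function(kind, size, weight = 1, ...) {
  if (size < 2) stop("`size` must be >= 2", call. = FALSE)
  m <- matrix(0, size, size)
  dots <- list(...)
  switch(kind,
    complete = { m[] <- weight; diag(m) <- 0 },
    ring = {
      for (i in seq_len(size)) {
        j <- if (i == size) 1L else i + 1L
        m[i, j] <- m[j, i] <- weight
      }
    },
    star = {
      m[1, 2:size] <- weight
      m[2:size, 1] <- weight
    },
    path = {
      for (i in seq_len(size - 1)) m[i, i + 1] <- m[i + 1, i] <- weight
    },
    two_cliques = {
      if (size %% 2 != 0) stop("`two_cliques` needs an even size", call. = FALSE)
      h <- size / 2
      m[1:h, 1:h] <- weight
      m[(h + 1):size, (h + 1):size] <- weight
      diag(m) <- 0
    },
    sbm = {
      bc <- dots$block_count %||% 2
      pw <- dots$p_within %||% 0.9
      pb <- dots$p_between %||% 0.05
      set.seed(derive_seed(dots$seed %||% 1, 53L))
      blocks <- sort(rep_len(seq_len(bc), size))
      for (i in seq_len(size - 1)) {
        for (j in (i + 1):size) {
          p <- if (blocks[i] == blocks[j]) pw else pb
          if (stats::runif(1) < p) m[i, j] <- m[j, i] <- weight
        }
      }
      attr(m, "blocks") <- blocks
    },
    stop(sprintf("unknown toy network kind '%s'", kind), call. = FALSE)
  )
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk as plain text
#'
#' Matrices are written one per subject as whitespace-delimited text,
#' metadata as a CSV with header `subject_id,age,sex,dataset,atlas`.
#'
#' @param cohort List of subject records from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the metadata data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               dataset = s$dataset, atlas = s$atlas,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (s in cohort) {
    utils::write.table(s$matrix, file.path(dir, paste0(s$subject_id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(meta)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `metadata.csv` and per-subject matrices.
#' @return A list of subject records.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    m <- as.matrix(utils::read.table(
      file.path(dir, paste0(meta$subject_id[i], ".txt"))))
    dimnames(m) <- NULL
    c(as.list(meta[i, ]), list(matrix = m))
  })
}
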