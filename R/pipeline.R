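# End-to-end orchestration: simulate -> preprocess -> metrics ->
# turning points -> epochs, under a single validated configuration with
# reproducible seeds and a stage manifest.

#' Build a pipeline configuration
#'
#' Defaults reproduce the study settings: fixed 10% density thresholding,
#' modularity resolution 0.6, degree-5 trajectory fits, gradient window 5,
#' gradient threshold 0.8, merging age window 5, and the full 968-member
#' UMAP grid ("default"; "small" is a 6-member grid for quick runs).
#'
#' @param mode Thresholding mode, `"fixed"` or `"variable"`.
#' @param target_density Fixed-mode target (default 0.10).
#' @param gamma Modularity resolution (default 0.6).
#' @param n_null Small-world null count (default 10).
#' @param grid `"default"`, `"small"`, or a data.frame from [umap_grid()].
#' @param degree,window,threshold,age_window Turning-point parameters
#'   (defaults 5, 5, 0.8, 5).
#' @param min_prominence KDE peak prominence fraction (default 0.05).
#' @param cohort A [synthetic_cohort_config()] describing the simulated
#'   cohort (default: 90-node cohort, 2 subjects per integer age).
#' @param seed Global seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixed", "variable"),
                            target_density = 0.10, gamma = 0.6, n_null = 10,
                            grid = "default", degree = 5, window = 5,
                            threshold = 0.8, age_window = 5,
                            min_prominence = 0.05, cohort = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (target_density <= 0 || target_density > 1) {
    stop("`target_density` must be in (0, 1]", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` (T) must be >= 0", call. = FALSE)
  if (window < 1) stop("`window` (W) must be >= 1", call. = FALSE)
  if (age_window < 1) stop("`age_window` (A) must be >= 1", call. = FALSE)
  if (degree < 2) stop("`degree` must be >= 2", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be > 0", call. = FALSE)
  if (is.null(cohort)) {
    cohort <- synthetic_cohort_config(
      n_subjects = 182, ages = rep(0:90, each = 2), seed = seed)
  }
  structure(list(mode = mode, target_density = target_density, gamma = gamma,
                 n_null = n_null, grid = grid, degree = degree,
                 window = window, threshold = threshold,
                 age_window = age_window, min_prominence = min_prominence,
                 cohort = cohort, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess (outlier removal, thresholding,
#' normalization), metrics, turning points and epoch characterization in
#' order. Each stage's key outputs and seeds are recorded in a manifest; a
#' stage failure halts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return A list with `cohort`, `metrics` (global + nodal tables),
#'   `turning_points`, `epochs` (assignment + correlation/LASSO/PCA/DTW
#'   reports) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(config = config, stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      completed = TRUE, seconds = as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))

  prep <- stage("preprocess", {
    flt <- remove_density_outliers(cohort)
    kept <- flt$kept
    if (config$mode == "fixed") {
      th <- threshold_to_density(lapply(kept, `[[`, "matrix"),
                                 config$target_density, mode = "fixed")
      for (i in seq_along(kept)) kept[[i]]$matrix <- th$matrices[[i]]
    } else {
      targets <- compute_variable_density_targets(kept)
      kept <- threshold_cohort_variable(kept, targets)
    }
    for (i in seq_along(kept)) {
      kept[[i]]$matrix <- normalize_weights(kept[[i]]$matrix)
    }
    list(kept = kept, removed = flt$removed_ids)
  })
  cohort <- prep$kept
  manifest$stages$preprocess_removed <- prep$removed

  metrics <- stage("metrics", cohort_metric_table(
    cohort, gamma = config$gamma, n_null = config$n_null, seed = config$seed))

  grid <- config$grid
  if (identical(grid, "default")) grid <- umap_grid(seed = config$seed)
  if (identical(grid, "small")) {
    grid <- umap_grid(nearest_neighbors = c(5, 15),
                      min_dist = c(0.1, 0.5, 1.0), seed = config$seed)
  }
  metric_cols <- c("avg_strength", "global_efficiency", "char_path_length",
                   "small_worldness", "modularity", "core_periphery",
                   "s_core", "avg_local_efficiency", "avg_clustering",
                   "avg_betweenness", "avg_subgraph_centrality")
  tp <- stage("turning_points", run_turning_point_pipeline(
    metrics$global, grid = grid, degree = config$degree,
    window = config$window, threshold = config$threshold,
    age_window = config$age_window, min_prominence = config$min_prominence,
    metric_cols = metric_cols))

  ep <- stage("epochs", {
    boundaries <- tp$major
    idx <- assign_epochs(metrics$global$age, boundaries)
    n_ep <- length(unique(idx))
    corr <- tryCatch(
      epoch_correlations(metrics$global, idx, metric_cols = metric_cols),
      error = function(e) {
        warning("epoch correlations skipped: ", conditionMessage(e)); NULL
      })
    lasso <- tryCatch(
      lasso_age_prediction(metrics$global, idx, metric_cols = metric_cols,
                           seed = config$seed),
      error = function(e) {
        warning("LASSO skipped: ", conditionMessage(e)); NULL
      })
    pca <- pca_parallel_varimax(metrics$global, metric_cols = metric_cols,
                                seed = config$seed)
    cmp <- dtwr <- NULL
    if (!is.null(pca$scores) && n_ep >= 2 &&
        all(table(idx) >= 3)) {
      cmp <- compare_epoch_scores(pca$scores, idx)
      dtwr <- tryCatch(
        dtw_epoch_trajectories(pca$scores, idx, metrics$global$age),
        error = function(e) {
          warning("DTW skipped: ", conditionMessage(e)); NULL
        })
    }
    list(boundaries = boundaries, assignment = idx, correlations = corr,
         lasso = lasso, pca = pca, comparison = cmp, dtw = dtwr)
  })

  list(cohort = cohort, metrics = metrics, turning_points = tp,
       epochs = ep, manifest = manifest)
}
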