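# Shared internal helpers.

#' Round half away from zero at integer precision
#'
#' Age bins use nearest-integer rounding with halves rounded up (e.g. 8.5
#' becomes 9), unlike [base::round()]'s banker's rounding.
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Validate a connectivity matrix
#'
#' A connectivity matrix must be square, symmetric, nonnegative and have a
#' zero diagonal. Used as a guard by every metric and preprocessing step.
#'
#' @param m Numeric matrix.
#' @param arg Name used in error messages.
#' @return Invisibly, `m`.
#' @export
check_connectivity_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be square", arg), call. = FALSE)
  }
  if (nrow(m) < 2) {
    stop(sprintf("`%s` must have at least 2 nodes", arg), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  if (any(m < 0)) {
    stop(sprintf("`%s` must be nonnegative", arg), call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  }
  invisible(m)
}

# Convert a connectivity matrix to an undirected weighted igraph graph.
as_weighted_graph <- function(m) {
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Deterministic 32-bit sub-seed derived from a global seed and integer keys.
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) {
    h <- (h * 31 + (as.numeric(k) %% 1000003)) %% 2147483629
  }
  as.integer(h)
}
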