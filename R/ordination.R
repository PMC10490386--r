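#' Non-metric multidimensional scaling with multiple random starts
#'
#' Embeds a dissimilarity matrix in `n_dimensions` by minimizing Kruskal's
#' stress-1, `sqrt(sum((dhat - d)^2) / sum(d^2))`, where `dhat` are the
#' monotone-regressed disparities and `d` the configuration distances
#' (primary treatment of ties). Each start draws a random initial
#' configuration and refines it with [vegan::monoMDS()]; the lowest-stress
#' solution over all starts is retained. Coordinates are centered and
#' rotated to principal axes, which leaves stress unchanged but fixes the
#' orientation for reproducibility.
#'
#' @param D Symmetric dissimilarity matrix or `dist`; needs at least
#'   `n_dimensions + 2` sites.
#' @param n_dimensions Embedding dimension (default 2).
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer seed governing all starts.
#' @param max_iter Maximum iterations per start (default 500).
#' @param tol Convergence tolerances passed to the optimizer (default
#'   1e-7).
#' @return An `nmds_result`: list with `coordinates` (n x k, centered,
#'   principal-axis oriented), `stress`, `n_starts`, `best_start_index`,
#'   `seed`, `converged`.
#' @export
nmds <- function(D, n_dimensions = 2L, n_starts = 100L, seed = 1L,
                 max_iter = 500L, tol = 1e-7) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  n <- attr(d, "Size")
  if (n < n_dimensions + 2L) stop("need at least n_dimensions + 2 sites")
  v <- as.vector(d)
  if (stats::var(v) == 0) {
    warning("degenerate dissimilarities: all pairwise values equal")
  }
  set.seed(seed)
  best <- NULL
  best_idx <- NA_integer_
  for (s in seq_len(n_starts)) {
    init <- matrix(stats::rnorm(n * n_dimensions), n, n_dimensions)
    fit <- vegan::monoMDS(d, y = init, k = n_dimensions, model = "global",
                          maxit = max_iter, smin = tol, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_idx <- s
    }
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  # principal-axis rotation: stress-invariant, fixes orientation
  coords <- coords %*% svd(coords)$v
  # sign convention: largest-magnitude loading positive per axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- attr(d, "Labels")
  colnames(coords) <- paste0("NMDS", seq_len(n_dimensions))
  res <- list(coordinates = coords, stress = best$stress,
              n_starts = as.integer(n_starts),
              best_start_index = best_idx, seed = as.integer(seed),
              converged = best$maxits == 0 || best$iters < max_iter)
  class(res) <- "nmds_result"
  res
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS in %d dimensions: stress = %.4f (best of %d starts)\n",
              ncol(x$coordinates), x$stress, x$n_starts))
  invisible(x)
}
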