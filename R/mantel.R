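#' Mantel correlation between two dissimilarity matrices
#'
#' Pearson correlation between the off-diagonal entries of two square
#' matrices over the same sites, with significance from a permutation null:
#' one matrix has its rows and columns simultaneously permuted
#' `n_permutations` times and the one-sided p-value is
#' `(1 + #\{null r >= observed r\}) / (1 + n_permutations)` (upper tail,
#' testing for positive association). The test is delegated to
#' [vegan::mantel()]; this wrapper fixes the seed, validates the inputs,
#' and returns a compact result.
#'
#' @param D1,D2 Symmetric numeric matrices (or `dist`) with identical site
#'   ordering; at least 4 sites.
#' @param n_permutations Number of matrix permutations (default 999).
#' @param seed Integer seed.
#' @param na_rm Drop pairs that are `NA` in either matrix (needed when one
#'   input is an SES matrix with degenerate pairs).
#' @return A `mantel_result` list: `r`, `p`, `n_permutations`, `seed`,
#'   `correlation_kind`.
#' @export
mantel_test <- function(D1, D2, n_permutations = 999L, seed = 1L,
                        na_rm = FALSE) {
  if (inherits(D1, "dist")) D1 <- as.matrix(D1)
  if (inherits(D2, "dist")) D2 <- as.matrix(D2)
  stopifnot(is.matrix(D1), is.matrix(D2))
  if (!all(dim(D1) == dim(D2))) stop("matrix size mismatch")
  if (nrow(D1) < 4L) stop("Mantel test needs at least 4 sites")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    stop("site orderings differ between the two matrices")
  }
  v1 <- D1[lower.tri(D1)]
  v2 <- D2[lower.tri(D2)]
  keep <- !(is.na(v1) | is.na(v2))
  if (!na_rm && any(!keep)) stop("NA dissimilarities; use na_rm = TRUE")
  if (stats::var(v1[keep]) == 0 || stats::var(v2[keep]) == 0) {
    stop("zero variance in a dissimilarity matrix: Mantel r undefined")
  }
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                       method = "pearson", permutations = n_permutations,
                       na.rm = na_rm)
  res <- list(r = unname(fit$statistic), p = unname(fit$signif),
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed),
              correlation_kind = "pearson")
  class(res) <- "mantel_result"
  res
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$correlation_kind, x$n_permutations))
  invisible(x)
}
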