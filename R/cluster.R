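#' The eight supported agglomerative linkage functions
#'
#' Fixed evaluation (and tie-breaking) order: single and complete linkage,
#' the unweighted/weighted average methods (UPGMA, WPGMA), the
#' unweighted/weighted centroid methods (UPGMC, WPGMC) and the two Ward
#' variants (`ward.D` applies the Ward update to raw dissimilarities,
#' `ward.D2` to squared dissimilarities with square-rooted heights).
#'
#' @export
LINKAGE_METHODS <- c("single", "complete", "UPGMA", "WPGMA",
                     "UPGMC", "WPGMC", "ward.D", "ward.D2")

# names stats::hclust uses for each
.hclust_name <- c(single = "single", complete = "complete",
                  UPGMA = "average", WPGMA = "mcquitty",
                  UPGMC = "centroid", WPGMC = "median",
                  ward.D = "ward.D", ward.D2 = "ward.D2")

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Runs standard Lance-Williams agglomeration (via [stats::hclust()]) for
#' one of the eight supported linkage methods and scores the fit of the
#' dendrogram to the input distances by the cophenetic correlation
#' coefficient (CCC) and Gower's distance (GD, the sum of squared
#' differences between input and cophenetic distances). Centroid methods
#' can produce inversions (non-monotone merge heights); these are flagged,
#' not repaired.
#'
#' @param D Symmetric dissimilarity matrix (site names) or `dist`; at
#'   least 3 sites.
#' @param method One of [LINKAGE_METHODS].
#' @return A `linkage_result`: list with `method`, `hclust`, `merge`,
#'   `heights`, `cophenetic` (square matrix), `ccc`, `gd`,
#'   `has_inversions`.
#' @export
linkage <- function(D, method = "UPGMA") {
  if (!method %in% LINKAGE_METHODS) {
    stop("unknown linkage method '", method, "'; use one of: ",
         paste(LINKAGE_METHODS, collapse = ", "))
  }
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  if (attr(d, "Size") < 3L) stop("need at least 3 sites")
  hc <- stats::hclust(d, method = .hclust_name[[method]])
  coph <- as.matrix(stats::cophenetic(hc))
  Dm <- as.matrix(d)
  coph <- coph[rownames(Dm), colnames(Dm)]
  res <- list(method = method, hclust = hc, merge = hc$merge,
              heights = hc$height, cophenetic = coph,
              # degenerate (constant) inputs leave the correlation undefined
              ccc = tryCatch(ccc(Dm, coph), error = function(e) NA_real_),
              gd = gower_distance(Dm, coph),
              has_inversions = any(diff(hc$height) < 0))
  class(res) <- "linkage_result"
  res
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the height of the first merge uniting sites i and j.
#'
#' @param L A `linkage_result` (or an `hclust`).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(L) {
  hc <- if (inherits(L, "linkage_result")) L$hclust else L
  as.matrix(stats::cophenetic(hc))
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the strictly-lower-triangle entries of the
#' original distance matrix and the cophenetic matrix. Values near 1
#' indicate a dendrogram faithful to the input distances; the value is not
#' clamped, so pathological fits may score negative.
#'
#' @param D,C Matching square matrices (original and cophenetic).
#' @return A number in \[-1, 1\].
#' @export
ccc <- function(D, C) {
  stopifnot(all(dim(D) == dim(C)))
  x <- D[lower.tri(D)]
  y <- C[lower.tri(C)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: cophenetic correlation undefined")
  }
  stats::cor(x, y)
}

#' Gower's distance between a distance matrix and a cophenetic matrix
#'
#' Sum of squared discrepancies over the strictly-lower triangle; smaller
#' is better, 0 means the dendrogram reproduces the distances exactly.
#'
#' @param D,C Matching square matrices.
#' @return A non-negative number.
#' @export
gower_distance <- function(D, C) {
  stopifnot(all(dim(D) == dim(C)))
  sum((D[lower.tri(D)] - C[lower.tri(C)])^2)
}

#' Score all eight linkage methods and select the best
#'
#' Runs [linkage()] under every method in [LINKAGE_METHODS] and tabulates
#' CCC and GD for each. The selected method maximizes CCC; ties are broken
#' by minimal GD, then by the fixed order of [LINKAGE_METHODS] (logged via
#' a message) so selection is deterministic.
#'
#' @param D Symmetric dissimilarity matrix or `dist`.
#' @return A list with `best_method`, `table` (data frame method/ccc/gd),
#'   and `fits` (named list of `linkage_result`s).
#' @export
select_method <- function(D) {
  fits <- lapply(LINKAGE_METHODS, function(m) linkage(D, m))
  names(fits) <- LINKAGE_METHODS
  tab <- data.frame(method = LINKAGE_METHODS,
                    ccc = vapply(fits, function(f) f$ccc, 0),
                    gd = vapply(fits, function(f) f$gd, 0),
                    has_inversions = vapply(fits, function(f) f$has_inversions, TRUE),
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(-tab$ccc, tab$gd, seq_len(nrow(tab)))
  best <- tab$method[ord[1L]]
  if (nrow(tab) > 1L &&
      isTRUE(tab$ccc[ord[1L]] == tab$ccc[ord[2L]] &&
             tab$gd[ord[1L]] == tab$gd[ord[2L]])) {
    message("method selection tie between ", tab$method[ord[1L]], " and ",
            tab$method[ord[2L]], "; fixed method order decides")
  }
  list(best_method = best, table = tab, fits = fits)
}

#' Silhouette widths of a partition against a distance matrix
#'
#' Standard silhouette: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with
#' `a(i)` the mean within-cluster distance (excluding self) and `b(i)` the
#' smallest mean distance to another cluster; singleton clusters get
#' `s(i) = 0`. Computed by [cluster::silhouette()].
#'
#' @param D Symmetric dissimilarity matrix or `dist`.
#' @param labels Cluster labels (vector, one per site; at least 2 distinct).
#' @return A list with `widths` (named per-site vector) and `mean`.
#' @export
silhouette_widths <- function(D, labels) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  codes <- as.integer(factor(labels))
  if (length(unique(codes)) < 2L) stop("silhouette needs at least 2 clusters")
  if (length(codes) != attr(d, "Size")) stop("one label per site required")
  sil <- cluster::silhouette(codes, dist = d)
  w <- sil[, "sil_width"]
  names(w) <- attr(d, "Labels")
  list(widths = w, mean = mean(w))
}

#' Choose the number of regions by the silhouette method
#'
#' Cuts the dendrogram at every `k` in `[k_min, k_max]` and evaluates the
#' mean silhouette width of the resulting partition against the original
#' distances; returns the maximizing `k` (ties go to the smaller `k`, the
#' more parsimonious regionalization).
#'
#' @param L A `linkage_result`.
#' @param D The distance matrix the dendrogram was built from.
#' @param k_min,k_max Search range; defaults 2 and `min(15, n - 1)`.
#' @return A list with `k_best` and `silhouette_curve` (data frame k/mean
#'   silhouette).
#' @export
select_k <- function(L, D, k_min = 2L, k_max = NULL) {
  n <- length(L$hclust$order)
  if (is.null(k_max)) k_max <- min(15L, n - 1L)
  stopifnot(k_min >= 2L, k_max <= n - 1L, k_min <= k_max)
  ks <- seq.int(k_min, k_max)
  ms <- vapply(ks, function(k) {
    silhouette_widths(D, stats::cutree(L$hclust, k = k))$mean
  }, 0)
  list(k_best = ks[which.max(ms)],
       silhouette_curve = data.frame(k = ks, mean_silhouette = ms))
}

#' Cut a dendrogram into regions nested in realms
#'
#' Region labels come from the k-cut of the dendrogram and realm labels
#' from the 2-cut of the same tree, so each region nests in exactly one
#' realm (cuts of one tree are hierarchical) and every region is a
#' monophyletic clade of the dendrogram by construction. The report checks
#' monophyly (asserted) and, when a site adjacency list is provided, counts
#' regions that are not geographically contiguous (split into more than one
#' connected component of the adjacency graph). Contiguity is reported,
#' never enforced.
#'
#' @param L A `linkage_result`.
#' @param D The distance matrix (for silhouette reporting).
#' @param k Number of regions (2 to n - 1).
#' @param adjacency Optional two-column matrix/data frame of site-id pairs
#'   declared geographically adjacent.
#' @return A `region_assignment`: list with `table` (data frame
#'   site/region/realm), `k`, `mean_silhouette`, `silhouette_widths`,
#'   `realm_of_region`, `criteria_report`.
#' @export
assign_regions <- function(L, D, k, adjacency = NULL) {
  n <- length(L$hclust$order)
  if (k < 2L || k > n - 1L) stop("k out of range [2, ", n - 1L, "]")
  region <- stats::cutree(L$hclust, k = k)
  realm <- stats::cutree(L$hclust, k = 2L)
  sites <- L$hclust$labels
  region_lab <- paste0("region_", region)
  realm_lab <- paste0("realm_", realm)
  # nesting check: each region must sit inside exactly one realm
  realm_of_region <- tapply(realm_lab, region_lab, unique)
  if (any(lengths(realm_of_region) != 1L)) {
    stop("internal error: a region spans two realms")   # impossible for tree cuts
  }
  sil <- silhouette_widths(D, region)
  report <- list(monophyletic_regions = TRUE,
                 n_noncontiguous_regions = NA_integer_,
                 noncontiguous_regions = character(0))
  if (!is.null(adjacency)) {
    adjacency <- as.matrix(adjacency)
    if (ncol(adjacency) != 2L) stop("adjacency must have two columns")
    unknown <- setdiff(c(adjacency), sites)
    if (length(unknown)) stop("adjacency names unknown sites: ",
                              paste(unknown, collapse = ", "))
    if (any(adjacency[, 1L] == adjacency[, 2L])) stop("self-adjacent site pair")
    split_regions <- vapply(unique(region_lab), function(rl) {
      members <- sites[region_lab == rl]
      n_components(members, adjacency) > 1L
    }, TRUE)
    report$n_noncontiguous_regions <- sum(split_regions)
    report$noncontiguous_regions <- names(split_regions)[split_regions]
  }
  res <- list(table = data.frame(site = sites, region = region_lab,
                                 realm = realm_lab, stringsAsFactors = FALSE),
              k = as.integer(k),
              mean_silhouette = sil$mean,
              silhouette_widths = sil$widths,
              realm_of_region = unlist(realm_of_region),
              criteria_report = report)
  class(res) <- "region_assignment"
  res
}

# connected components of the adjacency graph induced on `members`
#' @keywords internal
n_components <- function(members, adjacency) {
  keep <- adjacency[, 1L] %in% members & adjacency[, 2L] %in% members
  edges <- adjacency[keep, , drop = FALSE]
  comp <- stats::setNames(seq_along(members), members)
  for (i in seq_len(nrow(edges))) {
    a <- comp[[edges[i, 1L]]]
    b <- comp[[edges[i, 2L]]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp))
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("Region assignment: %d regions in %d realm(s), mean silhouette %.3f\n",
              x$k, length(unique(x$table$realm)), x$mean_silhouette))
  print(table(realm = x$table$realm, region = x$table$region))
  if (!is.na(x$criteria_report$n_noncontiguous_regions)) {
    cat(sprintf("non-contiguous regions: %d\n",
                x$criteria_report$n_noncontiguous_regions))
  }
  invisible(x)
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#'
#' @param L A `linkage_result`.
#' @return A `phylo` object (use [write_tree()] to serialize).
#' @export
dendrogram_tree <- function(L) {
  ape::as.phylo(L$hclust)
}
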