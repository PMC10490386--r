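#' Taxon-count components of pairwise compositional dissimilarity
#'
#' Given two taxon sets, returns the classical `a` (shared), `b` (unique to
#' the first) and `c` (unique to the second) counts on which the turnover
#' indices are built.
#'
#' @param x_i,x_j Character vectors of taxon identifiers.
#' @return A list with integer fields `a`, `b`, `c` and `basis =
#'   "taxon-count"`.
#' @export
taxon_components <- function(x_i, x_j) {
  x_i <- unique(x_i)
  x_j <- unique(x_j)
  a <- length(intersect(x_i, x_j))
  list(a = a, b = length(x_i) - a, c = length(x_j) - a,
       basis = "taxon-count")
}

#' Simpson turnover component
#'
#' The turnover (replacement) component of Sorensen dissimilarity,
#' `min(b, c) / (a + min(b, c))`: 0 for identical composition, 1 when no
#' taxa (or branch lengths) are shared, and 0 for strictly nested
#' communities. Insensitive to richness differences.
#'
#' @param comp A component list as returned by [taxon_components()] or
#'   [phylo_components()], or a list with fields `a`, `b`, `c`.
#' @return A number in \[0, 1\].
#' @export
beta_sim <- function(comp) {
  m <- min(comp$b, comp$c)
  denom <- comp$a + m
  if (denom == 0) stop("beta_sim undefined: both communities empty")
  m / denom
}

#' Jaccard-family turnover component
#'
#' The turnover component of Jaccard dissimilarity,
#' `2 min(b, c) / (a + 2 min(b, c))`; a monotone transform of [beta_sim()],
#' so the two induce the same pairwise ordering of sites.
#'
#' @inheritParams beta_sim
#' @return A number in \[0, 1\].
#' @export
beta_jtu <- function(comp) {
  m <- min(comp$b, comp$c)
  denom <- comp$a + 2 * m
  if (denom == 0) stop("beta_jtu undefined: both communities empty")
  2 * m / denom
}

#' Root-anchored phylogenetic diversity of a taxon set
#'
#' Sum of branch lengths over the union of root-to-tip paths of the given
#' taxa: Faith's PD anchored at the tree root (the stem path from the root
#' to the set's most recent common ancestor is included).
#'
#' @param taxa Character vector of tip labels (nonempty, all on the tree).
#' @param tree A rooted `phylo` with branch lengths.
#' @param anchor `"root"` (default) includes the path from the root to the
#'   set's MRCA; `"mrca"` excludes it.
#' @return A non-negative number.
#' @export
rooted_pd <- function(taxa, tree, anchor = c("root", "mrca")) {
  anchor <- match.arg(anchor)
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("empty taxon set")
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  }
  ei <- edge_incidence(tree)
  present <- logical(length(tree$tip.label))
  present[idx] <- TRUE
  on_path <- as.vector(crossprod(ei$tip_by_edge, present)) > 0
  if (anchor == "mrca" && length(taxa) >= 1L) {
    # drop edges ancestral to the MRCA: those subtending the whole set
    n_in <- as.vector(crossprod(ei$tip_by_edge, present))
    spans_all <- n_in == length(idx)
    on_path <- on_path & !spans_all
    # the MRCA-anchored PD of a single tip is 0 by this definition only if
    # every edge on its path spans the whole set, which is true; keep as is
  }
  sum(tree$edge.length[on_path])
}

#' Branch-length components of pairwise phylogenetic dissimilarity
#'
#' Decomposes the root-anchored phylogenetic diversity of two communities
#' into shared (`a`) and unique (`b`, `c`) branch lengths:
#' with `P_i`, `P_j` and `P_u` the PD of each community and of their union,
#' `a = P_i + P_j - P_u`, `b = P_u - P_j`, `c = P_u - P_i`, so that
#' `a + b + c = P_u`. Feeding these to [beta_sim()] or [beta_jtu()] gives
#' the phylogenetic turnover indices.
#'
#' @param x_i,x_j Nonempty character vectors of tip labels.
#' @param tree A rooted `phylo` with branch lengths.
#' @return A list with numeric fields `a`, `b`, `c` and `basis =
#'   "branch-length"`.
#' @export
phylo_components <- function(x_i, x_j, tree) {
  if (length(x_i) == 0L || length(x_j) == 0L) stop("empty community")
  p_i <- rooted_pd(x_i, tree)
  p_j <- rooted_pd(x_j, tree)
  p_u <- rooted_pd(union(x_i, x_j), tree)
  list(a = p_i + p_j - p_u, b = p_u - p_j, c = p_u - p_i,
       basis = "branch-length")
}

#' Tip-by-edge incidence of a rooted tree
#'
#' For each edge, which tips descend from it (equivalently, which tips'
#' root paths include it). Cached on the tree environment is not possible
#' for plain phylo objects, so callers looping over permutations should
#' compute this once and reuse it.
#'
#' @param tree A rooted `phylo`.
#' @return A list with `tip_by_edge` (n_tips x n_edges 0/1 matrix, tip rows
#'   in `tree$tip.label` order) and `lengths` (edge lengths).
#' @keywords internal
edge_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nedge <- nrow(edge)
  po <- ape::reorder.phylo(tree, "postorder")
  # accumulate descendant tip sets bottom-up over nodes
  nnode_total <- ntip + tree$Nnode
  desc <- vector("list", nnode_total)
  for (t in seq_len(ntip)) desc[[t]] <- t
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1L]
    child <- po$edge[k, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  tbe <- matrix(0, nrow = ntip, ncol = nedge)
  for (e in seq_len(nedge)) {
    tbe[desc[[edge[e, 2L]]], e] <- 1
  }
  rownames(tbe) <- tree$tip.label
  list(tip_by_edge = tbe, lengths = tree$edge.length)
}

#' Pairwise turnover dissimilarity matrix among sites
#'
#' Computes the full symmetric matrix of a turnover metric over all site
#' pairs of a presence-absence matrix. Taxonomic metrics (`"beta_sim"`,
#' `"beta_jtu"`) use taxon counts; phylogenetic metrics (`"pbeta_sim"`,
#' `"pbeta_jtu"`) use shared/unique root-anchored branch lengths on `tree`
#' and require the matrix and tree to be harmonized (see [harmonize()]).
#'
#' @param mat Site-by-taxon binary matrix; every site nonempty.
#' @param metric One of `"beta_sim"`, `"beta_jtu"`, `"pbeta_sim"`,
#'   `"pbeta_jtu"`.
#' @param tree Rooted `phylo`, required for the phylogenetic metrics.
#' @return A symmetric numeric matrix with zero diagonal, site names on
#'   both dimensions, and a `"metric"` attribute.
#' @export
pairwise_beta <- function(mat,
                          metric = c("beta_sim", "beta_jtu",
                                     "pbeta_sim", "pbeta_jtu"),
                          tree = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (any(rowSums(mat) == 0L)) stop("empty sites; run harmonize()/validation first")
  phylo <- metric %in% c("pbeta_sim", "pbeta_jtu")
  if (phylo) {
    if (is.null(tree)) stop("tree required for metric ", metric)
    if (!setequal(colnames(mat), tree$tip.label)) {
      stop("matrix taxa and tree tips differ; harmonize() first")
    }
    mat <- mat[, tree$tip.label, drop = FALSE]
    ei <- edge_incidence(tree)
    comp <- pair_components_phylo(mat, ei)
  } else {
    comp <- pair_components_taxon(mat)
  }
  turnover_from_components(comp, family = if (grepl("jtu", metric)) "jtu" else "sim",
                           metric_name = metric, sites = rownames(mat))
}

# shared (A), unique (B, C) taxon counts for all site pairs at once
#' @keywords internal
pair_components_taxon <- function(mat) {
  m <- mat
  storage.mode(m) <- "double"
  A <- tcrossprod(m)              # shared taxa
  rich <- rowSums(m)
  B <- matrix(rich, nrow(m), nrow(m)) - A          # unique to row site
  list(A = A, B = B, C = t(B))
}

# shared/unique branch lengths for all site pairs given an edge incidence
#' @keywords internal
pair_components_phylo <- function(mat, ei) {
  m <- mat
  storage.mode(m) <- "double"
  E <- (m %*% ei$tip_by_edge) > 0          # sites x edges: edge on some path
  storage.mode(E) <- "double"
  EL <- sweep(E, 2L, ei$lengths, "*")
  A <- tcrossprod(EL, E)                   # shared branch length
  pd <- as.vector(E %*% ei$lengths)
  B <- matrix(pd, nrow(m), nrow(m)) - A
  list(A = A, B = B, C = t(B))
}

#' @keywords internal
turnover_from_components <- function(comp, family, metric_name, sites) {
  M <- pmin(comp$B, comp$C)
  M[M < 0] <- 0                            # guard tiny negative rounding
  D <- if (family == "jtu") 2 * M / (comp$A + 2 * M) else M / (comp$A + M)
  D <- (D + t(D)) / 2                      # enforce exact symmetry
  diag(D) <- 0
  dimnames(D) <- list(sites, sites)
  attr(D, "metric") <- metric_name
  D
}

#' Per-site mean dissimilarity
#'
#' For each site, the mean of its dissimilarities to all other sites — the
#' quantity mapped per geographic unit when summarizing regional turnover.
#' `NA` entries (e.g. SES pairs with a degenerate null) are excluded.
#'
#' @param D A symmetric square matrix with site names.
#' @return A named numeric vector of per-site means.
#' @export
site_mean <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 2L) stop("need at least two sites")
  diag(D) <- NA_real_
  rowMeans(D, na.rm = TRUE)
}
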