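#' Read a rooted phylogenetic tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream turnover
#' machinery relies on: unique tip labels, exactly one root, and a finite
#' non-negative length on every edge. Branch lengths are required because
#' phylogenetic turnover is defined on shared branch lengths; trees without
#' them are rejected unless `default_length` supplies a uniform substitute
#' (useful only for purely topological exploration).
#'
#' @param path Path to a Newick file.
#' @param default_length Optional single non-negative number assigned to
#'   every edge when the file carries no branch lengths. Default `NULL`
#'   (reject such trees).
#' @return An object of class `phylo` (rooted, with `edge.length`).
#' @export
read_tree <- function(path, default_length = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) {
    if (is.null(default_length)) {
      stop("tree in ", path, " has no branch lengths; supply default_length ",
           "to assign unit lengths for topology-only use")
    }
    stopifnot(is.numeric(default_length), length(default_length) == 1L,
              default_length >= 0)
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  validate_tree(tree)
  tree
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(!is.finite(tree$edge.length))) {
    stop("every edge must have a finite branch length")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  invisible(tree)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a site-by-taxon presence-absence matrix
#'
#' Expects delimited text with the first column holding site identifiers and
#' the header row holding taxon identifiers; all cells must be 0 or 1. The
#' delimiter is auto-detected (tab or comma) unless given. Sites with no
#' present taxon and taxa present at no site are dropped, and the dropped
#' identifiers are reported via a message and the `"dropped_sites"` /
#' `"dropped_taxa"` attributes of the result.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` (default) auto-detects `\t` vs `,`
#'   from the header line.
#' @param transpose If `TRUE` the file is taxa-in-rows and is transposed
#'   on read.
#' @return An integer matrix with site row names and taxon column names.
#' @export
read_matrix <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate site ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate taxon ids in ", path)
  storage.mode(m) <- "double"
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop("non-binary cell at site '", rownames(m)[i], "', taxon '",
         colnames(m)[j], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- trimws(rownames(m))
  colnames(m) <- trimws(colnames(m))
  validate_matrix(m, report = TRUE)
}

#' @keywords internal
validate_matrix <- function(m, report = FALSE) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)))
  empty_sites <- rownames(m)[rowSums(m) == 0L]
  empty_taxa <- colnames(m)[colSums(m) == 0L]
  if (length(empty_sites) || length(empty_taxa)) {
    if (report) {
      if (length(empty_sites))
        message("dropping ", length(empty_sites), " empty site(s): ",
                paste(empty_sites, collapse = ", "))
      if (length(empty_taxa))
        message("dropping ", length(empty_taxa), " absent taxon/taxa: ",
                paste(empty_taxa, collapse = ", "))
    }
    m <- m[rowSums(m) > 0L, colSums(m) > 0L, drop = FALSE]
  }
  attr(m, "dropped_sites") <- empty_sites
  attr(m, "dropped_taxa") <- empty_taxa
  m
}

#' Write a presence-absence matrix as delimited text
#'
#' @param m Site-by-taxon integer matrix.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a tree and an occurrence matrix to their common taxa
#'
#' Empty sites and never-occurring taxa are dropped first; the tree is then
#' pruned to, and the matrix restricted to, the intersection of the
#' remaining taxon labels (exact match after trimming surrounding
#' whitespace). Pruning suppresses the resulting degree-2 internal nodes by
#' summing their incident branch lengths, and any stem lost between the
#' original root and the retained tips' MRCA is kept as an explicit root
#' edge, so root-to-tip path lengths of retained tips are preserved —
#' root-anchored phylogenetic diversity is therefore unchanged by
#' harmonization. Sites left empty by the restriction are dropped.
#'
#' @param tree A `phylo` object.
#' @param mat A site-by-taxon binary matrix.
#' @return A list with elements `tree`, `mat`, and `report` (character
#'   vectors `dropped_from_tree` and `dropped_from_matrix`; taxa occurring
#'   at no site are counted as dropped from both sides).
#' @export
harmonize <- function(tree, mat) {
  validate_tree(tree)
  tree$tip.label <- trimws(tree$tip.label)
  colnames(mat) <- trimws(colnames(mat))
  mat <- validate_matrix(mat, report = TRUE)
  common <- intersect(tree$tip.label, colnames(mat))
  if (length(common) == 0L) stop("tree and matrix share no taxon labels")
  dropped_tree <- setdiff(tree$tip.label, common)
  dropped_mat <- setdiff(colnames(mat), common)
  if (length(dropped_tree)) {
    tree <- prune_keep_depth(tree, common)
  }
  # restrict and reorder matrix columns to tree tip order; the restriction
  # can empty a site whose only taxa were absent from the tree
  mat <- mat[, tree$tip.label, drop = FALSE]
  mat <- validate_matrix(mat, report = TRUE)
  list(tree = tree, mat = mat,
       report = list(dropped_from_tree = sort(dropped_tree),
                     dropped_from_matrix = sort(dropped_mat)))
}

# prune to `keep`, preserving every retained tip's root-to-tip path length:
# if the kept tips' MRCA sits below the original root, the lost stem is
# reattached as a singleton root edge
#' @keywords internal
prune_keep_depth <- function(tree, keep) {
  ref <- keep[1L]
  d_old <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  t2 <- ape::keep.tip(tree, keep)
  d_new <- ape::node.depth.edgelength(t2)[match(ref, t2$tip.label)]
  delta <- d_old - d_new
  if (delta > 1e-12) {
    nt <- length(t2$tip.label)
    edge <- t2$edge
    edge[edge > nt] <- edge[edge > nt] + 1L
    t2$edge <- rbind(c(nt + 1L, nt + 2L), edge)
    t2$edge.length <- c(delta, t2$edge.length)
    t2$Nnode <- t2$Nnode + 1L
  }
  t2
}

#' Write a labeled square distance matrix as delimited text
#'
#' @param D A symmetric matrix with site row/column names, or a `dist`.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_distance <- function(D, path, sep = "\t") {
  if (inherits(D, "dist")) D <- as.matrix(D)
  df <- data.frame(site = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix written by [write_distance()]
#'
#' @param path Path to the file.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A symmetric numeric matrix.
#' @export
read_distance <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1L, check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Write region/realm assignments as a delimited table
#'
#' @param assignment A `region_assignment` object (see [assign_regions()])
#'   or a data frame with columns `site`, `region`, `realm`.
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_regions <- function(assignment, path, sep = "\t") {
  df <- if (inherits(assignment, "region_assignment")) {
    assignment$table
  } else {
    as.data.frame(assignment)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Serializes the structured summary of a pipeline run (linkage
#' method-selection table, Mantel results, SES tallies, NMDS stress, ...)
#' as machine-readable JSON. Scalars are unboxed and numbers written at
#' full precision so a rerun with the same configuration produces a
#' byte-identical file.
#'
#' @param summary A named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
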