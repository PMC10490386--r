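# Independent oracles used across the suite. These deliberately avoid the
# package's own edge-incidence machinery: tip paths come from ape::nodepath
# and set arithmetic from base R, so agreement is a genuine cross-check.

# brute-force a/b/c by element-wise membership over an explicit universe
oracle_taxon_components <- function(x_i, x_j, universe) {
  in_i <- universe %in% x_i
  in_j <- universe %in% x_j
  list(a = sum(in_i & in_j), b = sum(in_i & !in_j), c = sum(!in_i & in_j))
}

# edge-by-edge classification of shared / unique-i / unique-j branch length,
# using root-to-tip node paths from ape::nodepath
oracle_phylo_components <- function(x_i, x_j, tree) {
  root <- length(tree$tip.label) + 1L
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  edges_of <- function(taxa) {
    idx <- match(taxa, tree$tip.label)
    keys <- unlist(lapply(idx, function(t) {
      np <- ape::nodepath(tree, from = root, to = t)
      paste(np[-length(np)], np[-1])
    }))
    unique(keys)
  }
  e_i <- edges_of(x_i)
  e_j <- edges_of(x_j)
  len <- function(keys) sum(tree$edge.length[match(keys, edge_key)])
  list(a = len(intersect(e_i, e_j)),
       b = len(setdiff(e_i, e_j)),
       c = len(setdiff(e_j, e_i)))
}

# a 4-tip star phylogeny with unit branch lengths
star_tree <- function(n = 4, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

# multiset of (bipartition, length) pairs, for tree round-trip comparison:
# each edge keyed by the sorted labels of the smaller side of its split
bipartition_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  keys <- vapply(seq_len(nrow(tree$edge)), function(e) {
    node <- tree$edge[e, 2]
    tips <- if (node <= ntip) {
      tree$tip.label[node]
    } else {
      tree$tip.label[unlist(ape::prop.part(tree)[[node - ntip]])]
    }
    paste(sort(tips), collapse = "|")
  }, "")
  ord <- order(keys, tree$edge.length)
  data.frame(key = keys[ord], len = tree$edge.length[ord])
}

# occupancy with no relation to the tree: scramble which tip each occupancy
# profile belongs to, preserving all richness structure
decouple_from_tree <- function(mat) {
  colnames(mat) <- sample(colnames(mat))
  mat[, order(colnames(mat)), drop = FALSE]
}

# small Euclidean configuration -> distance matrix with site names
config_distances <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  dimnames(D) <- list(sprintf("p%02d", seq_len(nrow(D))),
                      sprintf("p%02d", seq_len(nrow(D))))
  D
}

# two tight, far-separated blocks of sites
two_block_distances <- function(n_per = 5, within = 0.01, between = 1) {
  n <- 2 * n_per
  D <- matrix(between, n, n)
  D[seq_len(n_per), seq_len(n_per)] <- within
  D[n_per + seq_len(n_per), n_per + seq_len(n_per)] <- within
  diag(D) <- 0
  dimnames(D) <- list(sprintf("b%02d", 1:n), sprintf("b%02d", 1:n))
  D
}
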