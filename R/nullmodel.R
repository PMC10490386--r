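#' Shuffle the tip labels of a phylogeny
#'
#' Returns a tree with identical topology and branch lengths whose tip
#' labels have been permuted uniformly at random — the randomization behind
#' the phylogenetic-turnover null model. It destroys the phylogenetic
#' identity of taxa while preserving tree shape, branch lengths, and every
#' site's composition (so taxonomic turnover is untouched).
#'
#' @param tree A `phylo` object.
#' @return A `phylo` with permuted tip labels.
#' @export
shuffle_tips <- function(tree) {
  tree$tip.label <- sample(tree$tip.label)
  tree
}

#' Standardized effect size of phylogenetic turnover under a tip-shuffle null
#'
#' Computes the observed pairwise phylogenetic turnover matrix, then
#' `n_permutations` replicates of it on tip-shuffled trees, and standardizes
#' each pair as `SES = (observed - null mean) / null sd` using the sample
#' (n-1) standard deviation of the null ensemble. Positive SES means more
#' phylogenetic turnover between the two sites than expected given their
#' taxonomic turnover; negative means less. Per-site summaries average the
#' SES of each site against all others, and sites are tallied as positive,
#' negative, and significant (|mean SES| > 1.96).
#'
#' Pairs whose null distribution is degenerate (`null sd = 0`, e.g. on a
#' star phylogeny where every labeling is equivalent) get `NA` SES and are
#' excluded from site means; their count is reported.
#'
#' @param mat Harmonized site-by-taxon binary matrix.
#' @param tree Harmonized rooted `phylo` with branch lengths.
#' @param metric Phylogenetic turnover metric for the ensemble
#'   (`"pbeta_sim"`, default, or `"pbeta_jtu"`).
#' @param n_permutations Number of tip permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param check_taxonomic If `TRUE`, verifies on the first permutation that
#'   taxonomic turnover is invariant under the shuffle (a sanity check;
#'   always true by construction).
#' @return An object of class `ses_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `ses` (square matrices), `site_mean_ses`,
#'   `site_mean_observed`, `n_permutations`, `seed`, `n_degenerate_pairs`,
#'   `n_sites_positive`, `n_sites_negative`, `n_sites_significant`.
#' @export
ses_pbeta <- function(mat, tree, metric = c("pbeta_sim", "pbeta_jtu"),
                      n_permutations = 999L, seed = 1L,
                      check_taxonomic = FALSE) {
  metric <- match.arg(metric)
  stopifnot(n_permutations >= 2L)
  if (!setequal(colnames(mat), tree$tip.label)) {
    stop("matrix taxa and tree tips differ; harmonize() first")
  }
  mat <- mat[, tree$tip.label, drop = FALSE]
  family <- if (metric == "pbeta_jtu") "jtu" else "sim"
  ei <- edge_incidence(tree)
  n <- nrow(mat)
  sites <- rownames(mat)

  observed <- turnover_from_components(pair_components_phylo(mat, ei),
                                       family, metric, sites)
  set.seed(seed)
  if (check_taxonomic) {
    perm <- sample.int(ncol(mat))
    d0 <- pairwise_beta(mat, "beta_sim")
    d1 <- pairwise_beta(mat[, perm, drop = FALSE], "beta_sim")
    stopifnot(max(abs(d0 - d1)) < 1e-12)
    set.seed(seed)   # the check must not perturb the permutation stream
  }
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  lo <- matrix(Inf, n, n)
  hi <- matrix(-Inf, n, n)
  for (p in seq_len(n_permutations)) {
    perm <- sample.int(ncol(mat))
    # permuting tip labels is equivalent to permuting occupancy columns
    dp <- turnover_from_components(
      pair_components_phylo(mat[, perm, drop = FALSE], ei), family, metric, sites)
    s1 <- s1 + dp
    s2 <- s2 + dp * dp
    lo <- pmin(lo, dp)
    hi <- pmax(hi, dp)
  }
  null_mean <- s1 / n_permutations
  null_var <- (s2 - n_permutations * null_mean^2) / (n_permutations - 1)
  null_var[null_var < 0] <- 0
  null_sd <- sqrt(null_var)
  # a constant null ensemble is degenerate exactly; the accumulator variance
  # can carry ~1e-16 floating residue, so detect constancy from the range
  null_sd[hi - lo <= 0] <- 0
  ses <- (observed - null_mean) / null_sd
  ses[null_sd == 0] <- NA_real_
  diag(ses) <- NA_real_
  n_degenerate <- (sum(null_sd == 0) - n) / 2   # off-diagonal degenerate pairs

  site_mean_ses <- rowMeans(ses, na.rm = TRUE)
  site_mean_ses[is.nan(site_mean_ses)] <- NA_real_
  valid <- !is.na(site_mean_ses)
  res <- list(observed = observed, null_mean = null_mean, null_sd = null_sd,
              ses = ses, metric = metric,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed),
              site_mean_ses = site_mean_ses,
              site_mean_observed = site_mean(observed),
              n_degenerate_pairs = as.integer(n_degenerate),
              n_sites_positive = sum(site_mean_ses[valid] > 0),
              n_sites_negative = sum(site_mean_ses[valid] < 0),
              n_sites_significant = sum(abs(site_mean_ses[valid]) > 1.96))
  class(res) <- "ses_result"
  res
}

#' @export
print.ses_result <- function(x, ...) {
  n <- nrow(x$observed)
  cat("Tip-shuffle SES of", x$metric, "\n")
  cat(sprintf("  %d sites, %d permutations (seed %d)\n",
              n, x$n_permutations, x$seed))
  cat(sprintf("  site mean SES: %d positive, %d negative, %d significant (|SES| > 1.96)\n",
              x$n_sites_positive, x$n_sites_negative, x$n_sites_significant))
  if (x$n_degenerate_pairs > 0) {
    cat(sprintf("  %d pair(s) with degenerate null (SES set NA)\n",
                x$n_degenerate_pairs))
  }
  invisible(x)
}
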