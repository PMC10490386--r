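#' Define a synthetic-flora scenario
#'
#' Bundles the parameters of the synthetic generator: a pure-birth
#' phylogeny of `n_tips` genera, and an occupancy matrix in which sites
#' belong to regions nested inside realms — affinity planted at two
#' hierarchical depths of the tree. Each realm occupies a deep subtree of
#' the phylogeny; each region within it has a focal clade. A site carries
#' its region's focal-clade tips with probability `p_focal`, the other
#' tips of its realm's subtree with probability `p_realm` (a mild realm
#' affinity, by default a twofold enrichment over background), and all
#' remaining tips with probability `p_background`; finally every cell
#' flips with probability `noise_flip`. The defaults describe a flora with
#' a clear two-realm, four-region structure at a scale (40 sites, 400
#' genera) where the full pipeline, including the 999-permutation null
#' model, runs at desk scale.
#'
#' @param n_tips Number of tree tips (genera); at least 3.
#' @param n_realms Number of realms (deep clusters); at least 2.
#' @param regions_per_realm Regions nested in each realm; at least 1.
#' @param sites_per_region Sites per region; at least 2.
#' @param p_focal Occupancy probability for a region's focal-clade tips,
#'   in (0, 1].
#' @param p_background Occupancy probability for tips outside the site's
#'   realm subtree, in \[0, 1), strictly below `p_focal`.
#' @param p_realm Occupancy probability for non-focal tips inside the
#'   site's realm subtree; default `min(2 * p_background, p_focal)`. Must
#'   lie in `[p_background, p_focal]`.
#' @param realm_depth_bias Probability that a realm's focal clades are
#'   confined to one deep subtree (a root-child subtree, realms placed on
#'   alternating sides of the root split); with the complement the realm
#'   may sit anywhere in the tree.
#' @param noise_flip Per-cell flip probability, in \[0, 0.5).
#' @param clade_band Focal-clade size band as fractions of `n_tips`
#'   (default `c(0.075, 0.15)`), keeping regional clades substantial and
#'   comparable in richness.
#' @param seed Integer seed for the generator.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_tips = 400L, n_realms = 2L,
                               regions_per_realm = 2L, sites_per_region = 10L,
                               p_focal = 0.9, p_background = 0.05,
                               p_realm = min(2 * p_background, p_focal),
                               realm_depth_bias = 1.0, noise_flip = 0.01,
                               clade_band = c(0.075, 0.15),
                               seed = 1L) {
  stopifnot(n_tips >= 3L, n_realms >= 2L, regions_per_realm >= 1L,
            sites_per_region >= 2L,
            p_focal > 0, p_focal <= 1,
            p_background >= 0, p_background < 1,
            p_focal > p_background,
            p_realm >= p_background, p_realm <= p_focal,
            realm_depth_bias >= 0, realm_depth_bias <= 1,
            noise_flip >= 0, noise_flip < 0.5,
            length(clade_band) == 2L, clade_band[1] <= clade_band[2])
  structure(list(n_tips = as.integer(n_tips), n_realms = as.integer(n_realms),
                 regions_per_realm = as.integer(regions_per_realm),
                 sites_per_region = as.integer(sites_per_region),
                 p_focal = p_focal, p_background = p_background,
                 p_realm = p_realm,
                 realm_depth_bias = realm_depth_bias, noise_flip = noise_flip,
                 clade_band = as.numeric(clade_band),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Starts from two lineages and repeatedly bifurcates a uniformly chosen
#' extant lineage, with exponential waiting times at total rate equal to the
#' current lineage count (per-lineage rate 1). A final waiting time is drawn
#' after the n-th tip appears, so the expected root-to-tip depth is
#' `sum(1/k, k = 2..n)`. All tips end at the same time: the tree is
#' ultrametric, as befits a dated phylogeny.
#'
#' @param n_tips Number of tips, at least 3.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed.
#' @return An ultrametric binary `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3L) stop("n_tips must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  max_nodes <- 2L * n_tips
  birth <- numeric(max_nodes)
  split_at <- rep(NA_real_, max_nodes)
  child1 <- integer(max_nodes)
  child2 <- integer(max_nodes)
  # ids 2 and 3 are the two root lineages, born at time 0
  extant <- c(2L, 3L)
  next_id <- 4L
  t_now <- 0
  while (length(extant) < n_tips) {
    k <- length(extant)
    t_now <- t_now + stats::rexp(1L, rate = k)
    pick <- extant[sample.int(k, 1L)]
    split_at[pick] <- t_now
    child1[pick] <- next_id
    child2[pick] <- next_id + 1L
    birth[next_id] <- t_now
    birth[next_id + 1L] <- t_now
    extant <- c(extant[extant != pick], next_id, next_id + 1L)
    next_id <- next_id + 2L
  }
  t_end <- t_now + stats::rexp(1L, rate = n_tips)

  tip_counter <- 0L
  build <- function(id) {
    if (is.na(split_at[id])) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.10g", tip_counter, t_end - birth[id])
    } else {
      len <- split_at[id] - birth[id]
      sprintf("(%s,%s):%.10g", build(child1[id]), build(child2[id]), len)
    }
  }
  nwk <- sprintf("(%s,%s);", build(2L), build(3L))
  tree <- ape::read.tree(text = nwk)
  validate_tree(tree)
  tree
}

#' Plant hierarchical realm/region structure on a phylogeny
#'
#' Selects, for each realm, `regions_per_realm` disjoint focal clades with
#' sizes inside the scenario's `clade_band` (clades are picked largest
#' first within the band, keeping regional richness comparable). With
#' probability `realm_depth_bias` a realm's clades are confined to one
#' root-child subtree, realms alternating between the two sides of the
#' root split, so realms separate at the deepest divergence; otherwise the
#' realm may sit anywhere disjoint from previously used clades. The
#' realm's subtree (the root-side subtree in the deep case, the MRCA clade
#' of its focal clades otherwise) receives the intermediate `p_realm`
#' occupancy, planting the two-depth affinity hierarchy.
#'
#' Occupancy is then sampled independently per site: focal tips at
#' `p_focal`, other realm-subtree tips at `p_realm`, the rest at
#' `p_background`, with a final per-cell flip at `noise_flip`. A site that
#' comes out empty is resampled, so the matrix is always pipeline-valid.
#'
#' @param tree A rooted binary `phylo` (e.g. from [simulate_tree()]).
#' @param scenario A [synthetic_scenario()] (its `seed` is not consumed
#'   here; seed the RNG or use [simulate_flora()]).
#' @return A list: `mat` (site-by-taxon 0/1 matrix), `truth` (data frame
#'   site/realm/region), `focal_clades` (list of tip-label vectors),
#'   `realm_clades` (list of tip-label vectors).
#' @export
plant_regions <- function(tree, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ntip <- length(tree$tip.label)
  n_clades <- scenario$n_realms * scenario$regions_per_realm
  ei <- edge_incidence(tree)
  clade_tips <- apply(ei$tip_by_edge, 2L, function(z) which(z > 0))
  if (is.matrix(clade_tips)) clade_tips <- as.list(as.data.frame(clade_tips))
  sizes <- vapply(clade_tips, length, 1L)
  node_edge <- match(seq_len(ntip + tree$Nnode), tree$edge[, 2L])
  root_children <- tree$edge[tree$edge[, 1L] == ntip + 1L, 2L]

  m_lo <- max(3L, ceiling(scenario$clade_band[1] * ntip))
  m_hi <- max(m_lo, floor(scenario$clade_band[2] * ntip))

  used <- logical(ntip)
  focal <- vector("list", n_clades)
  realm_clades <- vector("list", scenario$n_realms)
  for (r in seq_len(scenario$n_realms)) {
    go_deep <- stats::runif(1L) < scenario$realm_depth_bias
    pool <- if (go_deep) {
      side <- root_children[(r - 1L) %% 2L + 1L]
      clade_tips[[node_edge[side]]]
    } else {
      seq_len(ntip)
    }
    cand <- which(vapply(seq_along(clade_tips), function(e) {
      tt <- clade_tips[[e]]
      length(tt) >= m_lo && length(tt) <= m_hi &&
        all(tt %in% pool) && !any(used[tt])
    }, TRUE))
    picked <- pick_disjoint_maxmin(clade_tips, sizes, cand,
                                   scenario$regions_per_realm)
    if (length(picked) < scenario$regions_per_realm) {
      stop("scenario infeasible: cannot place ", scenario$regions_per_realm,
           " disjoint focal clades of ", m_lo, "-", m_hi, " tips for realm ", r)
    }
    for (j in seq_along(picked)) {
      focal[[(r - 1L) * scenario$regions_per_realm + j]] <- clade_tips[[picked[j]]]
    }
    realm_clades[[r]] <- if (go_deep) {
      pool
    } else {
      mrca_clade(tree, unlist(clade_tips[picked]), clade_tips, node_edge, ntip)
    }
    used[unlist(clade_tips[picked])] <- TRUE
  }

  n_sites <- n_clades * scenario$sites_per_region
  mat <- matrix(0L, n_sites, ntip,
                dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                tree$tip.label))
  realm_of_site <- rep(seq_len(scenario$n_realms),
                       each = scenario$regions_per_realm *
                         scenario$sites_per_region)
  region_of_site <- rep(seq_len(n_clades), each = scenario$sites_per_region)
  for (s in seq_len(n_sites)) {
    p <- rep(scenario$p_background, ntip)
    p[realm_clades[[realm_of_site[s]]]] <- scenario$p_realm
    p[focal[[region_of_site[s]]]] <- scenario$p_focal
    repeat {
      row <- as.integer(stats::runif(ntip) < p)
      if (scenario$noise_flip > 0) {
        flip <- stats::runif(ntip) < scenario$noise_flip
        row[flip] <- 1L - row[flip]
      }
      if (any(row == 1L)) break
    }
    mat[s, ] <- row
  }
  truth <- data.frame(site = rownames(mat),
                      realm = sprintf("R%d", realm_of_site),
                      region = sprintf("r%d", region_of_site),
                      stringsAsFactors = FALSE)
  list(mat = mat, truth = truth,
       focal_clades = lapply(focal, function(i) tree$tip.label[i]),
       realm_clades = lapply(realm_clades, function(i) tree$tip.label[i]))
}

# choose m pairwise-disjoint clades from `cand` maximizing the smallest
# clade size: regions then ride on comparably rich clades, which keeps the
# min-based turnover indices well behaved across regions
#' @keywords internal
pick_disjoint_maxmin <- function(clade_tips, sizes, cand, m) {
  if (length(cand) < m) return(integer(0))
  cand <- cand[order(sizes[cand], decreasing = TRUE)]
  dfs <- function(pool, chosen, taken) {
    if (length(chosen) == m) return(chosen)
    for (i in seq_along(pool)) {
      e <- pool[i]
      if (any(clade_tips[[e]] %in% taken)) next
      res <- dfs(pool[-seq_len(i)], c(chosen, e),
                 c(taken, clade_tips[[e]]))
      if (length(res)) return(res)
    }
    integer(0)
  }
  for (s in unique(sizes[cand])) {       # thresholds in decreasing order
    sel <- dfs(cand[sizes[cand] >= s], integer(0), integer(0))
    if (length(sel)) return(sel)
  }
  integer(0)
}

# tips of the smallest clade containing all of `tips`
#' @keywords internal
mrca_clade <- function(tree, tips, clade_tips, node_edge, ntip) {
  spanning <- which(vapply(seq_along(clade_tips), function(e) {
    all(tips %in% clade_tips[[e]])
  }, TRUE))
  if (!length(spanning)) return(seq_len(ntip))   # MRCA is the root
  sizes <- vapply(clade_tips[spanning], length, 1L)
  clade_tips[[spanning[which.min(sizes)]]]
}

#' Simulate a full synthetic flora
#'
#' Convenience wrapper: seeds the RNG from the scenario, simulates the tree
#' and plants the regional structure. A pure-birth tree can by chance lack
#' enough disjoint clades in the scenario's size band (e.g. a strongly
#' imbalanced root split); the simulation is then conditioned on
#' feasibility by drawing a fresh tree from the same RNG stream, up to
#' `max_tries` times, which keeps the wrapper deterministic per seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param max_tries Trees attempted before giving up (default 50).
#' @return A list with `tree`, `mat`, `truth`, `focal_clades`,
#'   `realm_clades`, `scenario`.
#' @export
simulate_flora <- function(scenario = synthetic_scenario(), max_tries = 50L) {
  set.seed(scenario$seed)
  for (i in seq_len(max_tries)) {
    tree <- simulate_tree(scenario$n_tips)
    planted <- tryCatch(plant_regions(tree, scenario), error = identity)
    if (!inherits(planted, "error")) {
      return(c(list(tree = tree, scenario = scenario), planted))
    }
  }
  stop("scenario infeasible after ", max_tries, " trees: ",
       conditionMessage(planted))
}
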