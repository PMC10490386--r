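three_site_D <- function() {
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  D
}

test_that("single and UPGMA linkage reproduce hand agglomeration", {
  D <- three_site_D()
  ls <- linkage(D, "single")
  expect_equal(ls$heights, c(1, 4))
  lu <- linkage(D, "UPGMA")
  expect_equal(lu$heights, c(1, (4 + 4) / 2))
  # first merge joins s1 and s2 in both
  expect_equal(sort(ls$merge[1, ]), c(-2, -1))
  expect_equal(cophenetic_matrix(ls)["s1", "s3"], 4)
  expect_equal(cophenetic_matrix(ls)["s1", "s2"], 1)
  expect_error(linkage(D, "nonsense"), "unknown linkage")
})

test_that("UPGMA is a fixed point on ultrametric distances", {
  tr <- simulate_tree(12, seed = 44)
  D <- as.matrix(stats::cophenetic(tr))   # ultrametric by construction
  L <- linkage(D, "UPGMA")
  expect_equal(L$cophenetic[rownames(D), colnames(D)], D, tolerance = 1e-10)
  expect_equal(L$ccc, 1, tolerance = 1e-10)
  expect_lt(L$gd, 1e-10)
  expect_false(L$has_inversions)
})

test_that("equal distances merge everything at the same height", {
  D <- matrix(0.6, 5, 5); diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:5), paste0("s", 1:5))
  for (m in c("single", "complete", "UPGMA", "WPGMA")) {
    expect_equal(linkage(D, m)$heights, rep(0.6, 4))
  }
})

test_that("fit scores behave as Pearson correlation and squared discrepancy", {
  tr <- simulate_tree(10, seed = 3)
  D <- as.matrix(stats::cophenetic(tr))
  expect_equal(ccc(D, D), 1)
  expect_equal(gower_distance(D, D), 0)
  C <- D + 0.1
  diag(C) <- 0
  n_pairs <- choose(nrow(D), 2)
  expect_equal(ccc(D, C), 1)
  expect_equal(gower_distance(D, C), 0.01 * n_pairs, tolerance = 1e-12)
  expect_gte(gower_distance(C, D), 0)
  Dc <- matrix(1, 4, 4); diag(Dc) <- 0
  expect_error(ccc(Dc, Dc), "zero variance")
})

test_that("select_method scores all eight linkages and picks by CCC then GD", {
  tr <- simulate_tree(12, seed = 44)
  D <- as.matrix(stats::cophenetic(tr))
  sel <- select_method(D)
  expect_equal(nrow(sel$table), 8L)
  expect_setequal(sel$table$method, LINKAGE_METHODS)
  expect_equal(sel$best_method, "UPGMA")
  expect_equal(max(sel$table$ccc), sel$table$ccc[sel$table$method == "UPGMA"])
})

test_that("silhouette widths follow the standard definition", {
  D <- two_block_distances()
  labels <- rep(1:2, each = 5)
  sil <- silhouette_widths(D, labels)
  expect_gt(sil$mean, 0.9)
  expect_error(silhouette_widths(D, rep(1, 10)), "2 clusters")

  # a site equidistant from its own and the nearest other cluster scores 0
  D4 <- matrix(0.4, 4, 4); diag(D4) <- 0
  dimnames(D4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  sil4 <- silhouette_widths(D4, c(1, 1, 2, 2))
  expect_equal(unname(sil4$widths), rep(0, 4))

  # singleton clusters score 0 by convention
  sil_single <- silhouette_widths(two_block_distances(), c(1, rep(2, 9)))
  expect_equal(unname(sil_single$widths[1]), 0)
})

test_that("silhouette-guided k recovers planted block counts", {
  D <- two_block_distances()
  L <- linkage(D, "UPGMA")
  ks <- select_k(L, D)
  expect_equal(ks$k_best, 2L)
  expect_equal(nrow(ks$silhouette_curve), min(15, nrow(D) - 1) - 2 + 1)

  fl <- simulate_flora(synthetic_scenario(p_focal = 0.95, p_background = 0.02,
                                          sites_per_region = 5, seed = 2))
  Dp <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  ks2 <- select_k(linkage(Dp, "UPGMA"), Dp)
  expect_equal(ks2$k_best, 4L)
})

test_that("regions nest inside realms and cuts refine monotonically", {
  fl <- simulate_flora(synthetic_scenario(sites_per_region = 5, seed = 2))
  D <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  L <- linkage(D, "UPGMA")
  a4 <- assign_regions(L, D, 4)
  expect_equal(length(unique(a4$table$region)), 4L)
  expect_equal(length(unique(a4$table$realm)), 2L)
  # each region lies wholly inside one realm
  expect_true(all(lengths(tapply(a4$table$realm, a4$table$region, unique)) == 1))
  # at k = 2 the region and realm partitions coincide
  a2 <- assign_regions(L, D, 2)
  expect_equal(unname(table(a2$table$region, a2$table$realm) > 0),
               matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  # cut-nesting: the k=6 partition refines the k=4 partition
  r6 <- stats::cutree(L$hclust, 6)
  r4 <- stats::cutree(L$hclust, 4)
  expect_true(all(lengths(tapply(r4, r6, unique)) == 1))
  expect_error(assign_regions(L, D, 1), "out of range")
  expect_error(assign_regions(L, D, nrow(D)), "out of range")
})

test_that("site-order permutation relabels but does not change the partition", {
  skip_if_not_installed("mclust")
  fl <- simulate_flora(synthetic_scenario(n_tips = 150, sites_per_region = 4,
                                          seed = 5))
  D <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  set.seed(1)
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  a <- assign_regions(linkage(D, "UPGMA"), D, 4)
  b <- assign_regions(linkage(Dp, "UPGMA"), Dp, 4)
  merged <- merge(a$table, b$table, by = "site")
  expect_equal(mclust::adjustedRandIndex(merged$region.x, merged$region.y), 1)
})

test_that("contiguity violations are counted against the adjacency list", {
  D <- two_block_distances(n_per = 3)   # sites b01..b06, two blocks
  L <- linkage(D, "UPGMA")
  # chain adjacency within each block, except b03 is only adjacent to the
  # other block: block 1 = {b01, b02, b03} splits into two islands
  adj <- rbind(c("b01", "b02"), c("b03", "b04"),
               c("b04", "b05"), c("b05", "b06"))
  a <- assign_regions(L, D, 2, adjacency = adj)
  expect_equal(a$criteria_report$n_noncontiguous_regions, 1L)
  expect_true(a$criteria_report$monophyletic_regions)
  # fully chained adjacency has no violations
  adj_ok <- rbind(c("b01", "b02"), c("b02", "b03"), c("b04", "b05"),
                  c("b05", "b06"), c("b04", "b06"))
  expect_equal(assign_regions(L, D, 2, adjacency = adj_ok)$
                 criteria_report$n_noncontiguous_regions, 0L)
  expect_error(assign_regions(L, D, 2, adjacency = rbind(c("b01", "zz"))),
               "unknown sites")
  expect_error(assign_regions(L, D, 2, adjacency = rbind(c("b01", "b01"))),
               "self-adjacent")
})
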