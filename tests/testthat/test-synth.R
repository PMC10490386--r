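test_that("simulate_tree yields ultrametric binary trees, deterministically", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))

  a <- simulate_tree(40, seed = 7)
  b <- simulate_tree(40, seed = 7)
  expect_equal(bipartition_lengths(a), bipartition_lengths(b))
  expect_error(simulate_tree(2), "at least 3")
})

test_that("mean root-to-tip depth matches the pure-birth expectation", {
  # E[depth] = sum_{k=2}^{n} 1/k: waits Exp(k) while k lineages, k = 2..n
  n <- 500
  reps <- 50
  set.seed(202)
  depths <- vapply(seq_len(reps), function(i) {
    tr <- simulate_tree(n)
    ape::node.depth.edgelength(tr)[1]
  }, 0)
  expected <- sum(1 / (2:n))
  # var of depth = sum 1/k^2; standard error over replicates
  se <- sqrt(sum(1 / (2:n)^2) / reps)
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("degenerate occupancy probabilities reproduce focal clades exactly", {
  sc <- synthetic_scenario(n_tips = 120, sites_per_region = 3,
                           p_focal = 1, p_background = 0, noise_flip = 0,
                           seed = 4)
  fl <- simulate_flora(sc)
  for (s in seq_len(nrow(fl$mat))) {
    region_idx <- as.integer(sub("r", "", fl$truth$region[s]))
    expect_setequal(colnames(fl$mat)[fl$mat[s, ] == 1],
                    fl$focal_clades[[region_idx]])
  }
})

test_that("noise-free, background-free floras separate realms strictly", {
  sc <- synthetic_scenario(n_tips = 150, sites_per_region = 3,
                           p_focal = 1, p_background = 0, noise_flip = 0,
                           seed = 11)
  fl <- simulate_flora(sc)
  D <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  same_region <- outer(fl$truth$region, fl$truth$region, "==")
  same_realm <- outer(fl$truth$realm, fl$truth$realm, "==")
  lt <- lower.tri(D)
  expect_true(min(D[lt & !same_realm]) >= max(D[lt & same_region]))
})

test_that("within-region taxonomic turnover is below between-realm turnover", {
  n_ok <- 0L
  for (sd in 1:10) {
    fl <- simulate_flora(synthetic_scenario(sites_per_region = 3, seed = sd))
    D <- pairwise_beta(fl$mat, "beta_sim")
    same_region <- outer(fl$truth$region, fl$truth$region, "==")
    same_realm <- outer(fl$truth$realm, fl$truth$realm, "==")
    lt <- lower.tri(D)
    n_ok <- n_ok + (mean(D[lt & same_region]) < mean(D[lt & !same_realm]))
  }
  expect_equal(n_ok, 10L)
})

test_that("the generator is deterministic under a fixed seed", {
  sc <- synthetic_scenario(n_tips = 80, sites_per_region = 2, seed = 21)
  f1 <- simulate_flora(sc)
  f2 <- simulate_flora(sc)
  expect_identical(f1$mat, f2$mat)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  expect_identical(f1$truth, f2$truth)
})

test_that("infeasible scenarios are reported rather than silently fudged", {
  tr <- star_tree(20)   # a star has no internal clades at all
  sc <- synthetic_scenario(n_tips = 20, sites_per_region = 2, seed = 1)
  expect_error(plant_regions(tr, sc), "infeasible")
})
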