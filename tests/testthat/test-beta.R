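test_that("taxon components match direct set arithmetic", {
  comp <- taxon_components(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(comp[c("a", "b", "c")], list(a = 2L, b = 1L, c = 1L))
  x <- c("A", "B", "C")
  expect_equal(taxon_components(x, x)[c("a", "b", "c")],
               list(a = 3L, b = 0L, c = 0L))

  universe <- paste0("g", 1:30)
  set.seed(42)
  for (i in 1:50) {
    x_i <- sample(universe, rbinom(1, 29, 0.4) + 1)
    x_j <- sample(universe, rbinom(1, 29, 0.4) + 1)
    got <- taxon_components(x_i, x_j)
    want <- oracle_taxon_components(x_i, x_j, universe)
    expect_equal(got$a, want$a)
    expect_equal(got$b, want$b)
    expect_equal(got$c, want$c)
  }
})

test_that("beta_sim and beta_jtu follow their closed forms", {
  expect_equal(beta_sim(list(a = 2, b = 1, c = 3)), 1 / 3)
  expect_equal(beta_sim(list(a = 5, b = 0, c = 7)), 0)    # nested
  expect_equal(beta_sim(list(a = 0, b = 4, c = 2)), 1)    # disjoint
  expect_equal(beta_jtu(list(a = 2, b = 1, c = 3)), 0.5)
  expect_equal(beta_jtu(list(a = 5, b = 0, c = 7)), 0)
  expect_equal(beta_jtu(list(a = 0, b = 4, c = 2)), 1)
  expect_error(beta_sim(list(a = 0, b = 0, c = 0)), "empty")
  expect_error(beta_jtu(list(a = 0, b = 0, c = 0)), "empty")
})

test_that("rooted PD sums the union of root-to-tip paths", {
  st <- star_tree(4)
  expect_equal(rooted_pd(c("t1", "t2"), st), 2)
  expect_equal(rooted_pd(st$tip.label, st), sum(st$edge.length))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(rooted_pd(c("A", "B"), tr), 3)    # A:1 + B:1 + stem:1
  expect_equal(rooted_pd("C", tr), 2)
  expect_error(rooted_pd(character(0), tr), "empty")
  expect_error(rooted_pd(c("A", "zz"), tr), "unknown")

  # independent reference: picante's Faith PD with the root included
  skip_if_not_installed("picante")
  tr2 <- simulate_tree(30, seed = 13)
  set.seed(14)
  for (i in 1:10) {
    taxa <- sample(tr2$tip.label, sample(2:25, 1))
    comm <- matrix(as.integer(tr2$tip.label %in% taxa), 1,
                   dimnames = list("s", tr2$tip.label))
    want <- picante::pd(comm, tr2, include.root = TRUE)$PD
    expect_equal(rooted_pd(taxa, tr2), want, tolerance = 1e-9)
  }
})

test_that("phylogenetic components agree with per-edge classification", {
  st <- star_tree(4)
  comp <- phylo_components(c("t1", "t2"), c("t2", "t3"), st)
  expect_equal(comp[c("a", "b", "c")], list(a = 1, b = 1, c = 1))
  expect_equal(beta_sim(comp), 0.5)

  same <- phylo_components(c("t1", "t2"), c("t1", "t2"), st)
  expect_equal(same[c("a", "b", "c")], list(a = 2, b = 0, c = 0))

  set.seed(31)
  tr <- simulate_tree(50)
  for (i in 1:15) {
    x_i <- sample(tr$tip.label, sample(2:40, 1))
    x_j <- sample(tr$tip.label, sample(2:40, 1))
    got <- phylo_components(x_i, x_j, tr)
    want <- oracle_phylo_components(x_i, x_j, tr)
    expect_equal(got$a, want$a, tolerance = 1e-9)
    expect_equal(got$b, want$b, tolerance = 1e-9)
    expect_equal(got$c, want$c, tolerance = 1e-9)
    # conservation: a + b + c equals the union's rooted PD
    expect_equal(got$a + got$b + got$c, rooted_pd(union(x_i, x_j), tr),
                 tolerance = 1e-9)
  }
})

test_that("MRCA-anchored PD drops the root-to-MRCA stem", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(rooted_pd(c("A", "B"), tr, anchor = "mrca"), 2)
  expect_equal(rooted_pd(c("A", "C"), tr, anchor = "root"),
               rooted_pd(c("A", "C"), tr, anchor = "mrca"))  # MRCA is the root
})

test_that("pairwise matrices match per-pair values and are symmetric", {
  sets <- list(s1 = c("A", "B", "C"), s2 = c("B", "C", "D"), s3 = c("D", "E"))
  taxa <- c("A", "B", "C", "D", "E")
  mat <- t(vapply(sets, function(s) as.integer(taxa %in% s), integer(5)))
  colnames(mat) <- taxa
  D <- pairwise_beta(mat, "beta_sim")
  expect_equal(D["s1", "s2"], beta_sim(taxon_components(sets$s1, sets$s2)))
  expect_equal(D["s1", "s3"], beta_sim(taxon_components(sets$s1, sets$s3)))
  expect_equal(D["s2", "s3"], beta_sim(taxon_components(sets$s2, sets$s3)))
  expect_identical(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), names(sets)))

  fl <- simulate_flora(synthetic_scenario(n_tips = 100, sites_per_region = 2,
                                          seed = 8))
  Dp <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  i <- 3; j <- 7
  x_i <- colnames(fl$mat)[fl$mat[i, ] == 1]
  x_j <- colnames(fl$mat)[fl$mat[j, ] == 1]
  expect_equal(Dp[i, j], beta_sim(phylo_components(x_i, x_j, fl$tree)),
               tolerance = 1e-12)
  expect_error(pairwise_beta(fl$mat, "pbeta_sim"), "tree required")
})

test_that("on a star phylogeny the phylogenetic metrics collapse to taxonomic", {
  st <- star_tree(12)
  set.seed(77)
  mat <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12,
                dimnames = list(paste0("s", 1:8), st$tip.label))
  mat[rowSums(mat) == 0, 1] <- 1L
  expect_lt(max(abs(pairwise_beta(mat, "pbeta_sim", st) -
                    pairwise_beta(mat, "beta_sim"))), 1e-12)
  expect_lt(max(abs(pairwise_beta(mat, "pbeta_jtu", st) -
                    pairwise_beta(mat, "beta_jtu"))), 1e-12)
})

test_that("Simpson and Jaccard turnover are monotone transforms of each other", {
  # beta_jtu = 2 s / (1 + s) with s = beta_sim, hence identical rankings
  fl <- simulate_flora(synthetic_scenario(n_tips = 100, sites_per_region = 3,
                                          seed = 15))
  Ds <- pairwise_beta(fl$mat, "beta_sim")
  Dj <- pairwise_beta(fl$mat, "beta_jtu")
  expect_equal(Dj, 2 * Ds / (1 + Ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  lt <- lower.tri(Ds)
  expect_equal(order(Ds[lt]), order(Dj[lt]))
  Dps <- pairwise_beta(fl$mat, "pbeta_sim", fl$tree)
  Dpj <- pairwise_beta(fl$mat, "pbeta_jtu", fl$tree)
  expect_equal(Dpj, 2 * Dps / (1 + Dps), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("site means average each site's dissimilarities to all others", {
  D2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(site_mean(D2), c(a = .4, b = .4))
  D3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D3["a", "b"] <- D3["b", "a"] <- 0.2
  D3["a", "c"] <- D3["c", "a"] <- 0.4
  D3["b", "c"] <- D3["c", "b"] <- 0.6
  expect_equal(site_mean(D3), c(a = 0.3, b = 0.4, c = 0.5))
  Dc <- matrix(0.7, 4, 4); diag(Dc) <- 0
  dimnames(Dc) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(site_mean(Dc)), rep(0.7, 4))
  expect_error(site_mean(D2[1, 1, drop = FALSE]), "two sites")
})
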