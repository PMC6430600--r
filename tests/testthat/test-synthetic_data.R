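test_that("Yule simulation is reproducible, rooted, binary, ultrametric", {
  t1 <- simulate_yule(20, seed = 99)
  t2 <- simulate_yule(20, seed = 99)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.rooted(t1))
  expect_true(ape::is.binary(t1))
  expect_true(ape::is.ultrametric(t1))
  expect_equal(t1$Nnode, 19L)  # n - 1 internal nodes on a rooted binary tree
  expect_equal(length(simulate_yule(2, seed = 1)$tip.label), 2L)
  expect_error(simulate_yule(1), ">= 2")
  # seeded call does not disturb the caller's RNG stream
  set.seed(5); a <- runif(1)
  set.seed(5); invisible(simulate_yule(5, seed = 123)); b <- runif(1)
  expect_identical(a, b)
})

test_that("branch-length distortion scales exactly the named clade", {
  set.seed(16)
  tree <- simulate_yule(12)
  # find a proper (non-root) clade to scale
  node <- tree$edge[which(tree$edge[, 2] > length(tree$tip.label))[1], 2]
  clade <- ape::extract.clade(tree, node)$tip.label
  same <- distort_branch_lengths(tree, list(list(tips = clade, factor = 1)))
  expect_equal(same$edge.length, tree$edge.length)
  scaled <- distort_branch_lengths(tree, list(
    list(tips = clade, factor = 0.02)))
  sub0 <- ape::extract.clade(tree, node)
  sub1 <- ape::extract.clade(scaled, ape::getMRCA(scaled, clade))
  expect_equal(sum(sub1$edge.length), 0.02 * sum(sub0$edge.length),
               tolerance = 1e-12)
  # paths between leaves outside the clade unchanged
  outside <- setdiff(tree$tip.label, clade)
  if (length(outside) >= 2) {
    d0 <- ape::cophenetic.phylo(tree)[outside, outside]
    d1 <- ape::cophenetic.phylo(scaled)[outside, outside]
    expect_equal(d1, d0, tolerance = 1e-12)
  }
  # a non-clade leaf set is rejected
  non_clade <- c(clade[1], setdiff(tree$tip.label, clade)[1])
  expect_error(distort_branch_lengths(tree, list(
    list(tips = non_clade, factor = 2))), "not a clade")
})

test_that("Mk trait simulator matches its per-branch change probability", {
  tree <- parse_newick("(A:1,B:1);")
  expect_equal(unname(simulate_mk_trait(tree, 0, root_state = 1, seed = 1)),
               c(1, 1))
  # empirical change frequency on a fixed branch vs (1 - exp(-2qt))/2
  q <- 0.7; t <- 0.8
  one <- parse_newick(sprintf("(A:%f,B:1e-12);", t))
  set.seed(26)
  n_rep <- 3000
  flips <- replicate(n_rep, simulate_mk_trait(one, q, root_state = 0)[["A"]])
  p_expect <- 0.5 * (1 - exp(-2 * q * t))
  se <- sqrt(p_expect * (1 - p_expect) / n_rep)
  expect_lt(abs(mean(flips) - p_expect), 3 * se)
  # very high rate: tips approach Bernoulli(1/2)
  set.seed(27)
  high <- replicate(1000, simulate_mk_trait(one, 100, root_state = 0)[["A"]])
  expect_lt(abs(mean(high) - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("BM trait simulator has Brownian moments", {
  tree <- parse_newick("(A:2,B:2);")
  expect_equal(unname(simulate_bm_trait(tree, 0, root_value = 3, seed = 1)),
               c(3, 3))
  set.seed(36)
  n_rep <- 2000
  sims <- replicate(n_rep, simulate_bm_trait(tree, 1.5))
  # tip variance = sigma2 * depth; chi-square 3-se band
  v <- var(sims["A", ])
  expect_lt(abs(v - 3), 3 * 3 * sqrt(2 / (n_rep - 1)))
  # sister covariance = sigma2 * shared path length
  cherry <- parse_newick("((A:1,B:1):1.5,C:2.5);")
  sims2 <- replicate(n_rep, simulate_bm_trait(cherry, 1))
  cv <- cov(sims2["A", ], sims2["B", ])
  expect_lt(abs(cv - 1.5), 3 * sqrt((2 * 2.5^2) / n_rep))
})

test_that("fixture bundle is complete, deterministic, and GC-targeted", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_study_fixture(d1, seed = 4)
  fx2 <- make_study_fixture(d2, seed = 4)
  expect_equal(nrow(fx1$traits), 55L)
  expect_equal(ncol(fx1$traits), 26L)  # taxon + 13 discrete + 12 continuous
  expect_true(ape::is.binary(fx1$tree_a))
  expect_identical(fx1$tree_a$tip.label, fx1$tree_b$tip.label)

  # byte-identical bundles under a fixed seed
  for (f in c("treeA.nwk", "treeB.nwk", "traits.tsv", "rules.yaml",
              file.path("fragments", "frag1.fasta"))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # different seed changes the bundle
  fx3 <- make_study_fixture(withr::local_tempdir(), seed = 5)
  expect_false(identical(write_newick(fx1$tree_a), write_newick(fx3$tree_a)))

  # G/C exemplars hit their targets within binomial tolerance
  g <- gc_report(fx1$fragments)
  expect_lt(abs(g$gc[g$taxon == "G4_sp01"] - 0.27), 0.02)
  expect_lt(abs(g$gc[g$taxon == "G2_sp01"] - 0.61), 0.02)
  expect_equal(g$taxon[which.min(g$gc)], "G4_sp01")
  expect_equal(g$taxon[which.max(g$gc)], "G2_sp01")

  # the focal trait is confined to group 4
  x <- binarize(stats::setNames(fx1$traits$d01, fx1$traits$taxon),
                c(yes = 1, no = 0))
  expect_true(all(x[fx1$groups[names(x)] != "G4"] == 0))
  expect_gte(sum(x[fx1$groups[names(x)] == "G4"]), 6)
})
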