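test_that("GLS root estimate matches closed forms", {
  tr2 <- parse_newick("(A:1,B:1);")
  expect_equal(fit_bm(tr2, c(A = 0, B = 2))$root_estimate, 1)

  # C = [[2,1,0],[1,2,0],[0,0,2]]; a = (1'C^-1 x)/(1'C^-1 1) = 16/7
  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(fit_bm(tr3, c(A = 0, B = 2, C = 4))$root_estimate, 16 / 7,
               tolerance = 1e-12)

  # polytomies are rejected with a clear error
  expect_error(
    fit_bm(parse_newick("((A:1,B:1,C:1):1,D:1);"),
           c(A = 0, B = 1, C = 2, D = 3)),
    "binary")
})

test_that("node estimates match the joint-normal conditional-mean oracle", {
  set.seed(12)
  for (i in 1:30) {
    tree <- ape::rtree(sample(4:6, 1))
    x <- stats::setNames(rnorm(length(tree$tip.label)), tree$tip.label)
    fit <- fit_bm(tree, x)
    asr <- ancestral_estimates(tree, x, fit)
    oracle <- bm_conditional_oracle(fit$tree, x)
    expect_equal(asr$estimate, unname(oracle[as.character(asr$node)]),
                 tolerance = 1e-8)
    # BM estimates interpolate: inside the tip range
    expect_true(all(asr$estimate >= min(x) - 1e-10 &
                    asr$estimate <= max(x) + 1e-10))
  }
})

test_that("estimates match the reference implementation, variances by n/(n-1)", {
  set.seed(22)
  tree <- ape::rtree(12)
  x <- stats::setNames(rnorm(12), tree$tip.label)
  fit <- fit_bm(tree, x)
  asr <- ancestral_estimates(tree, x, fit)
  ref <- phytools::fastAnc(tree, x, vars = TRUE)
  expect_equal(asr$estimate, unname(ref$ace[as.character(asr$node)]),
               tolerance = 1e-8)
  # the reference divides the rate by n-1 contrasts; this package uses ML (n)
  expect_equal(unname(ref$var[as.character(asr$node)]) / asr$variance,
               rep(12 / 11, nrow(asr)), tolerance = 1e-8)
})

test_that("scaling and shifting tips transforms estimates equivariantly", {
  set.seed(32)
  tree <- simulate_yule(15)
  x <- simulate_bm_trait(tree, 1)
  a0 <- ancestral_estimates(tree, x, fit_bm(tree, x))
  a_scaled <- ancestral_estimates(tree, 3 * x, fit_bm(tree, 3 * x))
  expect_equal(a_scaled$estimate, 3 * a0$estimate, tolerance = 1e-10)
  expect_equal(a_scaled$variance, 9 * a0$variance, tolerance = 1e-10)
  a_shift <- ancestral_estimates(tree, x + 5, fit_bm(tree, x + 5))
  expect_equal(a_shift$estimate, a0$estimate + 5, tolerance = 1e-10)
  expect_equal(a_shift$variance, a0$variance, tolerance = 1e-10)
})

test_that("degenerate data, intervals, and missing policy behave", {
  set.seed(42)
  tree <- simulate_yule(8)
  xc <- stats::setNames(rep(2.5, 8), tree$tip.label)
  fit <- fit_bm(tree, xc)
  expect_equal(fit$sigma2, 0)
  asr <- ancestral_estimates(tree, xc, fit)
  expect_equal(asr$estimate, rep(2.5, nrow(asr)))
  expect_equal(asr$variance, rep(0, nrow(asr)))

  x <- simulate_bm_trait(tree, 1)
  asr2 <- ancestral_estimates(tree, x, fit_bm(tree, x))
  expect_true(all(asr2$variance >= 0))
  expect_equal(asr2$ci_upper - asr2$estimate, asr2$estimate - asr2$ci_lower,
               tolerance = 1e-12)
  expect_equal(asr2$ci_upper, asr2$estimate + 1.959964 * sqrt(asr2$variance))
  # root row agrees with the fit
  f <- fit_bm(tree, x)
  expect_equal(asr2$estimate[asr2$node == 9], f$root_estimate)

  x[2] <- NA
  fitp <- fit_bm(tree, x)
  expect_equal(length(fitp$tree$tip.label), 7L)
  expect_error(fit_bm(tree, x, missing = "strict"), "missing trait values")

  # log10 option transforms the analysis scale
  xp <- stats::setNames(10^seq(1, 8), tree$tip.label)
  fl <- fit_bm(tree, xp, log10_transform = TRUE)
  expect_true(fl$root_estimate >= 1 && fl$root_estimate <= 8)
})

test_that("mean node variance is plain arithmetic with an informative error", {
  asr <- data.frame(variance = c(1, 3))
  expect_equal(mean_node_variance(asr), 2)
  expect_equal(mean_node_variance(data.frame(variance = rep(0.7, 5))), 0.7)
  expect_error(mean_node_variance(data.frame(variance = numeric(0))),
               "no interior-node variances")
})
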