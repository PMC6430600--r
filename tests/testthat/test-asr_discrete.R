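test_that("transition matrix matches the matrix-exponential oracle and its limits", {
  m <- mk_model(1, "ER")
  expect_equal(mk_transition_matrix(m, 0), diag(2), ignore_attr = TRUE)
  expect_equal(unname(mk_transition_matrix(m, 1e6)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  P <- mk_transition_matrix(m, 0.5)
  expect_equal(P[1, 1], 0.5 * (1 + exp(-1)))  # 0.6839397...
  expect_error(mk_transition_matrix(m, -1), ">= 0")

  set.seed(11)
  for (i in 1:10) {
    rates <- exp(runif(2, -2, 1))
    mod <- mk_model(rates, "ARD")
    t <- runif(1, 0, 3)
    Q <- matrix(c(-rates[1], rates[1], rates[2], -rates[2]), 2, 2, byrow = TRUE)
    expect_equal(unname(mk_transition_matrix(mod, t)),
                 as.matrix(Matrix::expm(Q * t)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(mk_transition_matrix(mod, t)), c(`0` = 1, `1` = 1))
  }
})

test_that("pruning log-likelihood matches exhaustive enumeration", {
  # two leaves, branches 0.5, ER q = 1, flat prior, tips (0, 1):
  # L = 0.5 * 2 * P(stay) * P(change) = 0.216166, logL = -1.5317
  tr <- parse_newick("(A:0.5,B:0.5);")
  m <- mk_model(1, "ER")
  ps <- 0.5 * (1 + exp(-1)); pc <- 1 - ps
  expect_equal(mk_loglik(tr, c(A = 0, B = 1), m), log(ps * pc),
               tolerance = 1e-12)
  expect_equal(mk_loglik(tr, c(A = 0, B = 1), m), -1.5317, tolerance = 1e-4)

  set.seed(21)
  for (i in 1:25) {
    tree <- ape::rtree(sample(4:6, 1))
    x <- random_binary_states(tree)
    mod <- mk_model(exp(runif(1, -2, 1)), "ER",
                    root_prior = if (i %% 2) "flat" else c(0.3, 0.7))
    expect_equal(mk_loglik(tree, x, mod), enum_mk_oracle(tree, x, mod)$loglik,
                 tolerance = 1e-10)
  }

  # vanishing rate with identical tips: logL -> log(prior of that state)
  tr4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x1 <- c(A = 1, B = 1, C = 1, D = 1)
  expect_equal(mk_loglik(tr4, x1, mk_model(1e-9, "ER", c(0.3, 0.7))),
               log(0.7), tolerance = 1e-6)
  expect_error(mk_loglik(tr4, c(A = 0, B = 1, C = 0), m), "without a state")
})

test_that("ER likelihood with a flat root prior is invariant under re-rooting", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    tree <- simulate_yule(n)
    x <- random_binary_states(tree)
    mod <- mk_model(exp(runif(1, -1.5, 0.5)), "ER")
    ll0 <- mk_loglik(tree, x, mod)
    for (v in seq.int(n + 1L, n + tree$Nnode)) {
      expect_equal(mk_loglik(reroot_at(tree, v), x, mod), ll0,
                   tolerance = 1e-10)
    }
  }
})

test_that("rate fitting maximizes the likelihood and flags boundaries", {
  set.seed(41)
  tree <- simulate_yule(30)
  x <- simulate_mk_trait(tree, 0.5)
  fit <- fit_mk(tree, x)
  expect_s3_class(fit, "mk_fit")
  expect_lte(fit$log_likelihood, 0)
  # attained maximum beats a dense grid of probed rates
  grid <- exp(seq(log(1e-6), log(1e3), length.out = 50))
  lls <- vapply(grid, function(q) mk_loglik(fit$tree, x, mk_model(q, "ER")),
                numeric(1))
  expect_gte(fit$log_likelihood, max(lls) - 1e-8)

  # invariant character: boundary fit, not an exception
  xs <- stats::setNames(rep(1, 30), tree$tip.label)
  bfit <- fit_mk(tree, xs)
  expect_true(bfit$boundary)

  # two opposite leaves push the rate to the upper bound; logL -> log(1/4)
  tr2 <- parse_newick("(A:0.5,B:0.5);")
  f2 <- fit_mk(tr2, c(A = 0, B = 1))
  expect_true(f2$boundary)
  expect_equal(f2$log_likelihood, log(0.25), tolerance = 1e-4)

  # ARD fit is at least as good as the nested ER fit
  set.seed(42)
  xa <- simulate_mk_trait(tree, 0.8)
  if (length(unique(xa)) > 1) {
    expect_gte(fit_mk(tree, xa, "ARD")$log_likelihood,
               fit_mk(tree, xa, "ER")$log_likelihood - 1e-6)
  }
})

test_that("missing tip states are pruned or rejected per policy", {
  set.seed(51)
  tree <- simulate_yule(12)
  x <- simulate_mk_trait(tree, 0.5)
  x[c(2, 5)] <- NA
  fit <- fit_mk(tree, x)
  expect_equal(sort(fit$tree$tip.label),
               sort(names(x)[!is.na(x)]))
  expect_error(fit_mk(tree, x, missing = "strict"), "missing trait values")

  # reconstruction refuses a tree/fit leaf-set mismatch
  other <- simulate_yule(8, seed = 3)
  expect_error(marginal_asr(other, simulate_mk_trait(other, 0.5), fit),
               "leaf sets differ")
})

test_that("marginal reconstruction equals brute-force marginalization", {
  set.seed(61)
  for (i in 1:30) {
    tree <- ape::rtree(sample(4:6, 1))
    x <- random_binary_states(tree)
    fit <- fit_mk(tree, x)
    asr <- marginal_asr(tree, x, fit)
    expect_equal(rowSums(as.matrix(asr[, c("p0", "p1")])),
                 rep(1, nrow(asr)), tolerance = 1e-10)
    oracle <- enum_mk_oracle(fit$tree, x, fit$model)
    expect_equal(unname(as.matrix(asr[, c("p0", "p1")])),
                 unname(oracle$post), tolerance = 1e-8)
  }
})

test_that("marginal reconstruction agrees with the reference implementation", {
  set.seed(71)
  tree <- ape::rtree(10)
  x <- random_binary_states(tree)
  fit <- fit_mk(tree, x)
  asr <- marginal_asr(tree, x, fit)
  ref <- phytools::rerootingMethod(tree, stats::setNames(factor(x), names(x)),
                                   model = "ER")
  expect_equal(fit$model$rates[["q01"]], ref$Q[1, 2], tolerance = 1e-4)
  expect_equal(fit$log_likelihood, ref$loglik, tolerance = 1e-6)
  mine <- as.matrix(asr[, c("p0", "p1")])
  theirs <- unname(ref$marginal.anc[as.character(asr$node), ])
  expect_equal(unname(mine), theirs, tolerance = 1e-6)
})

test_that("uniform tip data give symmetric root posteriors; uniform state pulls all nodes", {
  tr2 <- parse_newick("(A:0.5,B:0.5);")
  fit <- fit_mk(tr2, c(A = 0, B = 1))
  asr <- marginal_asr(tr2, c(A = 0, B = 1), fit)
  expect_equal(asr$p1, 0.5, tolerance = 1e-10)

  set.seed(81)
  tree <- simulate_yule(10)
  x1 <- stats::setNames(rep(1, 10), tree$tip.label)
  fit1 <- structure(list(model = mk_model(0.3, "ER"), log_likelihood = NA,
                         boundary = FALSE, tree = clamp_branch_lengths(tree),
                         tip_states = x1),
                    class = "mk_fit")
  asr1 <- marginal_asr(tree, x1, fit1)
  expect_true(all(asr1$p1 > 0.5))
})
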