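#' Fit Brownian motion to a continuous trait by maximum likelihood
#'
#' Generalized-least-squares closed form: with `C` the phylogenetic
#' covariance (shared root-to-tip path lengths) the root state is
#' `a = (1' C^-1 1)^-1 1' C^-1 x` and the ML rate is
#' `sigma2 = (x - a 1)' C^-1 (x - a 1) / n` (ML, i.e. divided by `n`, not
#' REML). Tips with missing values are pruned (`missing = "prune"`) or
#' raise an error (`missing = "strict"`). Zero-length branches are clamped
#' so that `C` stays invertible.
#'
#' @param tree Rooted, strictly binary `phylo` with branch lengths.
#' @param x Named numeric vector of tip values (NA allowed under `"prune"`).
#' @param missing `"prune"` or `"strict"`.
#' @param log10_transform If `TRUE`, `log10(x)` is analyzed (values must be
#'   positive). Default `FALSE`: traits are analyzed on the given scale.
#' @return Object of class `bm_fit`: list with `sigma2`, `root_estimate`,
#'   `tree` (pruned analysis tree), `x`.
#' @export
fit_bm <- function(tree, x, missing = c("prune", "strict"),
                   log10_transform = FALSE) {
  missing <- match.arg(missing)
  .assert_binary_rooted(tree, "Brownian-motion fitting")
  pr <- .prune_missing(tree, x, missing)
  tree <- clamp_branch_lengths(pr$tree)
  x <- pr$x
  if (log10_transform) {
    if (any(x <= 0)) stop("log10 transform requires positive trait values",
                          call. = FALSE)
    x <- log10(x)
  }
  est <- .bm_gls_root(tree, x)
  structure(list(sigma2 = est$sigma2, root_estimate = est$a,
                 tree = tree, x = x),
            class = "bm_fit")
}

# GLS root estimate and ML sigma^2 on one (rooted) tree
.bm_gls_root <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  U <- tryCatch(chol(C), error = function(e) {
    stop("phylogenetic covariance is singular: ", conditionMessage(e),
         call. = FALSE)
  })
  ones <- rep(1, length(x))
  Ci1 <- backsolve(U, backsolve(U, ones, transpose = TRUE))
  Cix <- backsolve(U, backsolve(U, x, transpose = TRUE))
  denom <- sum(Ci1)
  a <- sum(Cix) / denom
  r <- x - a
  Cir <- backsolve(U, backsolve(U, r, transpose = TRUE))
  list(a = unname(a), sigma2 = max(0, sum(r * Cir) / length(x)),
       inv_info = 1 / denom)
}

#' @export
print.bm_fit <- function(x, ...) {
  cat("Brownian-motion fit\n")
  cat("  sigma^2:", format(x$sigma2, digits = 8), "\n")
  cat("  root estimate:", format(x$root_estimate, digits = 8), "\n")
  invisible(x)
}

#' Ancestral state estimates under Brownian motion
#'
#' The estimate at each internal node is the GLS root estimate of the tree
#' re-rooted at that node; its variance is `sigma2_hat * (1' C_v^-1 1)^-1`
#' with `C_v` the covariance of the re-rooted tree and `sigma2_hat` taken
#' from the fit (no rate uncertainty is propagated). The 95% confidence
#' interval is `estimate +/- 1.959964 * sqrt(variance)`.
#'
#' @param tree The tree the fit was obtained on.
#' @param x Tip values the fit was obtained on.
#' @param fit A [fit_bm()] result.
#' @return Object of class `continuous_asr`: data frame with columns
#'   `node`, `estimate`, `variance`, `ci_lower`, `ci_upper` (one row per
#'   internal node, ape numbering of the analysis tree); `sigma2` attached
#'   as an attribute.
#' @export
ancestral_estimates <- function(tree, x, fit) {
  stopifnot(inherits(fit, "bm_fit"))
  obs <- names(x)[!is.na(x)]
  if (!setequal(intersect(obs, tree$tip.label), fit$tree$tip.label)) {
    stop("tree/fit mismatch: leaf sets differ", call. = FALSE)
  }
  tree <- fit$tree
  xv <- fit$x
  ntip <- length(tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  est <- var <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    rt <- reroot_at(tree, nodes[i])
    g <- .bm_gls_root(rt, xv)
    est[i] <- g$a
    var[i] <- fit$sigma2 * g$inv_info
  }
  z <- 1.959964
  out <- data.frame(node = nodes, estimate = est, variance = var,
                    ci_lower = est - z * sqrt(var),
                    ci_upper = est + z * sqrt(var))
  attr(out, "sigma2") <- fit$sigma2
  class(out) <- c("continuous_asr", "data.frame")
  out
}

#' Mean node variance of a continuous reconstruction
#'
#' The arithmetic mean of the per-node estimate variances — the relative
#' goodness-of-fit score used to compare how confidently two trees
#' reconstruct the same continuous trait.
#'
#' @param asr A [ancestral_estimates()] result (or any data frame with a
#'   `variance` column).
#' @return A single number.
#' @export
mean_node_variance <- function(asr) {
  v <- asr$variance
  if (is.null(v) || !length(v)) {
    stop("no interior-node variances to average", call. = FALSE)
  }
  mean(v)
}
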