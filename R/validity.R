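#' Binarize a raw discrete trait column
#'
#' Applies an explicit category-to-{0,1} rule; missing values pass through
#' unchanged. Any non-missing raw value without a rule entry is an error,
#' so silent recodings cannot occur.
#'
#' @param x Vector of raw trait values (character, factor, or 0/1).
#' @param rule Named vector or list mapping each raw category to 0 or 1.
#' @return Numeric vector of 0/1 with `NA` preserved, named as `x`.
#' @examples
#' binarize(c("yes", "no", NA), c(yes = 1, no = 0))
#' @export
binarize <- function(x, rule) {
  nm <- names(x)
  x <- as.character(x)
  rule <- unlist(rule)
  if (!all(rule %in% c(0, 1))) stop("rule values must be 0 or 1", call. = FALSE)
  out <- rep(NA_real_, length(x))
  obs <- !is.na(x) & x != ""
  uncovered <- setdiff(unique(x[obs]), names(rule))
  if (length(uncovered)) {
    stop("binarization rule does not cover value(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  out[obs] <- as.numeric(rule[x[obs]])
  names(out) <- nm
  out
}

#' Compare the Mk fit of one binary trait on two rival trees
#'
#' Both trees are pruned to the same per-trait taxon set (shared leaves
#' with observed states) so the log-likelihoods are commensurable, then the
#' Mk model is fitted independently on each (rates re-estimated per tree).
#' The tree with the higher (less negative) log-likelihood is favoured;
#' differences below `tie_tol` count as a tie.
#'
#' @param tree_a,tree_b Rooted binary `phylo` objects on the same species.
#' @param x Named binary trait vector (NA allowed).
#' @param model_class,root_prior Passed to [fit_mk()].
#' @param tie_tol Absolute log-likelihood difference treated as a tie.
#' @return List with `loglik_a`, `loglik_b`, `delta` (a - b), `favoured`
#'   (`"A"`, `"B"` or `"tie"`), `n_taxa`, and the two fits.
#' @export
compare_discrete <- function(tree_a, tree_b, x, model_class = "ER",
                             root_prior = "flat", tie_tol = 1e-6) {
  taxa <- .shared_observed_taxa(tree_a, tree_b, x)
  xa <- x[taxa]
  ta <- ape::keep.tip(tree_a, taxa)
  tb <- ape::keep.tip(tree_b, taxa)
  fa <- fit_mk(ta, xa, model_class = model_class, root_prior = root_prior)
  fb <- fit_mk(tb, xa, model_class = model_class, root_prior = root_prior)
  delta <- fa$log_likelihood - fb$log_likelihood
  favoured <- if (abs(delta) < tie_tol) "tie" else if (delta > 0) "A" else "B"
  list(loglik_a = fa$log_likelihood, loglik_b = fb$log_likelihood,
       delta = delta, favoured = favoured, n_taxa = length(taxa),
       fit_a = fa, fit_b = fb)
}

#' Compare Brownian-motion reconstructions of one trait on two rival trees
#'
#' Fits BM and reconstructs ancestral states on each tree (pruned to the
#' shared observed taxa), then compares the mean node variances; the ratio
#' A/B below 1 means tree A reconstructs the trait more confidently.
#'
#' @inheritParams compare_discrete
#' @param log10_transform Passed to [fit_bm()].
#' @return List with `mean_var_a`, `mean_var_b`, `ratio` (A/B), `n_taxa`,
#'   and the two `continuous_asr` objects.
#' @export
compare_continuous <- function(tree_a, tree_b, x, log10_transform = FALSE) {
  taxa <- .shared_observed_taxa(tree_a, tree_b, x)
  xa <- x[taxa]
  ta <- ape::keep.tip(tree_a, taxa)
  tb <- ape::keep.tip(tree_b, taxa)
  fa <- fit_bm(ta, xa, log10_transform = log10_transform)
  fb <- fit_bm(tb, xa, log10_transform = log10_transform)
  aa <- ancestral_estimates(ta, xa, fa)
  ab <- ancestral_estimates(tb, xa, fb)
  list(mean_var_a = mean_node_variance(aa), mean_var_b = mean_node_variance(ab),
       ratio = variance_ratio(aa, ab), n_taxa = length(taxa),
       asr_a = aa, asr_b = ab)
}

.shared_observed_taxa <- function(tree_a, tree_b, x) {
  obs <- names(x)[!is.na(x)]
  taxa <- Reduce(intersect, list(obs, tree_a$tip.label, tree_b$tip.label))
  if (length(taxa) < 3L) {
    stop("fewer than 3 shared taxa with observed trait values", call. = FALSE)
  }
  taxa
}

#' Ratio of mean node variances between two reconstructions
#'
#' @param asr_a,asr_b [ancestral_estimates()] results for the same trait on
#'   two trees.
#' @return `mean_node_variance(asr_a) / mean_node_variance(asr_b)`.
#' @export
variance_ratio <- function(asr_a, asr_b) {
  den <- mean_node_variance(asr_b)
  if (den == 0) stop("zero mean node variance in the denominator tree",
                     call. = FALSE)
  mean_node_variance(asr_a) / den
}

#' Summarize a two-tree validity comparison
#'
#' From per-trait discrete log-likelihood pairs and continuous variance
#' ratios, computes the arbitration summary: how many traits favour each
#' tree, the mean absolute log-likelihood advantage within each favoured
#' class (ties excluded from both counts and means), and the grand mean of
#' the continuous variance ratios.
#'
#' @param discrete Data frame with columns `trait`, `loglik_a`, `loglik_b`
#'   (may be `NULL` or empty).
#' @param continuous Data frame with columns `trait`, `ratio` (may be
#'   `NULL` or empty).
#' @param tie_tol Absolute log-likelihood difference treated as a tie.
#' @return List with `n_favour_a`, `n_favour_b`, `n_ties`,
#'   `mean_advantage_a`, `mean_advantage_b` (NA when no trait favours that
#'   tree), and `mean_variance_ratio` (NA when no continuous traits).
#' @export
summarize_validity <- function(discrete = NULL, continuous = NULL,
                               tie_tol = 1e-6) {
  out <- list(n_favour_a = 0L, n_favour_b = 0L, n_ties = 0L,
              mean_advantage_a = NA_real_, mean_advantage_b = NA_real_,
              mean_variance_ratio = NA_real_)
  if (!is.null(discrete) && nrow(as.data.frame(discrete))) {
    d <- as.data.frame(discrete)
    stopifnot(all(c("loglik_a", "loglik_b") %in% names(d)))
    delta <- d$loglik_a - d$loglik_b
    tie <- abs(delta) < tie_tol
    out$n_ties <- sum(tie)
    fav_a <- !tie & delta > 0
    fav_b <- !tie & delta < 0
    out$n_favour_a <- sum(fav_a)
    out$n_favour_b <- sum(fav_b)
    if (any(fav_a)) out$mean_advantage_a <- mean(abs(delta[fav_a]))
    if (any(fav_b)) out$mean_advantage_b <- mean(abs(delta[fav_b]))
  }
  if (!is.null(continuous) && nrow(as.data.frame(continuous))) {
    cc <- as.data.frame(continuous)
    stopifnot("ratio" %in% names(cc), all(cc$ratio > 0))
    out$mean_variance_ratio <- mean(cc$ratio)
  }
  out
}
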