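#' Two-state Mk model
#'
#' Continuous-time Markov model of a binary character on a tree. `ER` has a
#' single transition rate `q` in both directions; `ARD` has separate rates
#' `q01` (0 to 1) and `q10` (1 to 0). Rates are per unit branch length.
#'
#' @param rates Numeric: length 1 (`ER`) or 2, `c(q01, q10)` (`ARD`).
#' @param model_class `"ER"` or `"ARD"`.
#' @param root_prior `"flat"` (1/2, 1/2), `"stationary"`, or a probability
#'   vector of length 2 over states (0, 1).
#' @return An object of class `mk_model`.
#' @export
mk_model <- function(rates, model_class = c("ER", "ARD"), root_prior = "flat") {
  model_class <- match.arg(model_class)
  rates <- as.numeric(rates)
  if (model_class == "ER") {
    stopifnot(length(rates) == 1L)
    rates <- c(q01 = rates, q10 = rates)
  } else {
    stopifnot(length(rates) == 2L)
    names(rates) <- c("q01", "q10")
  }
  if (any(rates <= 0)) stop("Mk rates must be > 0", call. = FALSE)
  pi <- .resolve_root_prior(root_prior, rates)
  structure(list(model_class = model_class, rates = rates, root_prior = pi),
            class = "mk_model")
}

.resolve_root_prior <- function(root_prior, rates) {
  if (is.character(root_prior)) {
    pi <- switch(root_prior,
      flat = c(0.5, 0.5),
      stationary = c(rates[["q10"]], rates[["q01"]]) / sum(rates),
      stop("unknown root prior: ", root_prior, call. = FALSE)
    )
  } else {
    pi <- as.numeric(root_prior)
    stopifnot(length(pi) == 2L, all(pi >= 0))
    if (abs(sum(pi) - 1) > 1e-12) stop("root prior must sum to 1", call. = FALSE)
  }
  names(pi) <- c("0", "1")
  pi
}

#' Mk transition probability matrix
#'
#' Closed form for the two-state chain with rates `q01`, `q10`:
#' `P(t) = Pi + exp(-(q01+q10) t) (I - Pi)` where `Pi` has the stationary
#' distribution in its rows. For `ER` with rate `q`,
#' `P(stay) = (1 + exp(-2 q t)) / 2`.
#'
#' @param model An [mk_model()].
#' @param t Branch length, `>= 0`.
#' @return 2x2 row-stochastic matrix, rows/cols named `"0"`, `"1"`.
#' @export
mk_transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "mk_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("branch length t must be a single number >= 0", call. = FALSE)
  }
  a <- model$rates[["q01"]]; b <- model$rates[["q10"]]
  s <- a + b
  e <- exp(-s * t)
  P <- matrix(c(
    (b + a * e) / s, (a - a * e) / s,
    (b - b * e) / s, (a + b * e) / s
  ), nrow = 2, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
  P
}

# Internal pruning engine. Works on any rooted tree (multifurcations fine).
# tipL: ntip x 2 matrix of tip conditional likelihoods. Per-edge scaling
# keeps partials in range on large trees; returns total log-likelihood and
# (unlogged, rescaled) root conditionals.
.mk_pruning <- function(tree, tipL, model) {
  ntip <- nrow(tipL)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- pmax(po$edge.length, 1e-8)
  a <- model$rates[["q01"]]; b <- model$rates[["q10"]]
  s <- a + b
  e <- exp(-s * elen)
  # row-stochastic P(t) entries per edge
  p00 <- (b + a * e) / s; p01 <- 1 - p00
  p11 <- (a + b * e) / s; p10 <- 1 - p11
  nn <- ntip + tree$Nnode
  L0 <- c(tipL[, 1L], rep(1, tree$Nnode))
  L1 <- c(tipL[, 2L], rep(1, tree$Nnode))
  logscale <- 0
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    m0 <- p00[k] * L0[ch] + p01[k] * L1[ch]
    m1 <- p10[k] * L0[ch] + p11[k] * L1[ch]
    sc <- m0 + m1
    if (sc <= 0) return(list(loglik = -Inf, root_conditionals = c(0, 0)))
    L0[p] <- L0[p] * (m0 / sc)
    L1[p] <- L1[p] * (m1 / sc)
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  pi <- model$root_prior
  lik <- unname(pi[1L] * L0[root] + pi[2L] * L1[root])
  list(loglik = log(lik) + logscale,
       root_conditionals = c(`0` = unname(L0[root]), `1` = unname(L1[root])))
}

.tip_likelihoods <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  if (anyNA(st)) {
    stop("leaf without a state: ",
         paste(tree$tip.label[is.na(st)], collapse = ", "), call. = FALSE)
  }
  if (!all(st %in% c(0, 1))) stop("tip states must be 0 or 1", call. = FALSE)
  tipL <- matrix(0, ntip, 2)
  tipL[cbind(seq_len(ntip), st + 1L)] <- 1
  tipL
}

#' Mk log-likelihood of tip data on a tree
#'
#' Felsenstein pruning: post-order conditional likelihoods with per-edge
#' scaling, root prior applied at the root. Branch lengths of zero are
#' clamped to `1e-8`.
#'
#' @param tree Rooted `phylo` (binary; internally re-rooted trees with a
#'   basal trifurcation are also accepted).
#' @param tip_states Named vector of 0/1 states covering every leaf.
#' @param model An [mk_model()].
#' @return Total log-likelihood (a finite negative number).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "mk_model"))
  tipL <- .tip_likelihoods(tree, tip_states)
  .mk_pruning(tree, tipL, model)$loglik
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' The transition rate (ER) or rate pair (ARD) is maximized on a bounded
#' log scale, `log(q)` in `[log(1e-6), log(1e3)]`, with a deterministic
#' coarse grid followed by local refinement (tolerance 1e-8 on the
#' log-likelihood scale). Tips with missing states are pruned from the tree
#' before fitting (`missing = "prune"`, the default) or raise an error
#' (`missing = "strict"`). If all observed tips share one state the rate is
#' returned at the lower bound with `boundary = TRUE` rather than an error.
#'
#' @param tree Rooted, strictly binary `phylo`.
#' @param tip_states Named vector of states in `{0, 1, NA}`.
#' @param model_class `"ER"` or `"ARD"`.
#' @param root_prior See [mk_model()].
#' @param missing `"prune"` or `"strict"`.
#' @return An object of class `mk_fit`: list with `model`, `log_likelihood`,
#'   `boundary`, `tree` (the pruned analysis tree), `tip_states`.
#' @export
fit_mk <- function(tree, tip_states, model_class = c("ER", "ARD"),
                   root_prior = "flat", missing = c("prune", "strict")) {
  model_class <- match.arg(model_class)
  missing <- match.arg(missing)
  .assert_binary_rooted(tree, "Mk fitting")
  pr <- .prune_missing(tree, tip_states, missing)
  tree <- pr$tree; tip_states <- pr$x
  tree <- clamp_branch_lengths(tree)
  tipL <- .tip_likelihoods(tree, tip_states)

  lb <- log(1e-6); ub <- log(1e3)
  obj1 <- function(lq) {
    m <- mk_model(exp(lq), "ER", root_prior)
    -.mk_pruning(tree, tipL, m)$loglik
  }
  boundary <- FALSE
  if (length(unique(tip_states)) < 2L) {
    # invariant character: likelihood increases monotonically as q -> 0
    rates <- exp(lb)
    model <- mk_model(rates, "ER", root_prior)
    if (model_class == "ARD") model <- mk_model(c(rates, rates), "ARD", root_prior)
    ll <- .mk_pruning(tree, tipL, model)$loglik
    boundary <- TRUE
  } else if (model_class == "ER") {
    grid <- seq(lb, ub, length.out = 25L)
    vals <- vapply(grid, obj1, numeric(1))
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(obj1, c(lo, hi), tol = 1e-8)
    lq <- opt$minimum
    # flag fits pinned at (or on a plateau reaching) the search bounds
    if (lq - lb < 1e-2 || ub - lq < 1e-2 ||
        obj1(lb) < opt$objective + 1e-6 || obj1(ub) < opt$objective + 1e-6) {
      boundary <- TRUE
    }
    model <- mk_model(exp(lq), "ER", root_prior)
    ll <- -opt$objective
  } else {
    obj2 <- function(lq) {
      m <- mk_model(exp(lq), "ARD", root_prior)
      -.mk_pruning(tree, tipL, m)$loglik
    }
    starts <- list(c(-2, -2), c(0, 0), c(log(0.1), log(1)))
    best <- NULL
    for (s in starts) {
      o <- stats::optim(s, obj2, method = "L-BFGS-B", lower = lb, upper = ub,
                        control = list(factr = 1e3))
      if (is.null(best) || o$value < best$value) best <- o
    }
    lq <- best$par
    if (any(lq - lb < 1e-4) || any(ub - lq < 1e-4)) boundary <- TRUE
    model <- mk_model(exp(lq), "ARD", root_prior)
    ll <- -best$value
  }
  structure(list(model = model, log_likelihood = unname(ll),
                 boundary = boundary, tree = tree, tip_states = tip_states),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$model$model_class, ")\n", sep = "")
  cat("  rates:", paste(sprintf("%s = %.6g", names(x$model$rates),
                                x$model$rates), collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8), "\n")
  if (x$boundary) cat("  note: rate estimate at search boundary\n")
  invisible(x)
}

.prune_missing <- function(tree, x, missing) {
  x <- x[tree$tip.label]
  names(x) <- tree$tip.label
  drop <- tree$tip.label[is.na(x)]
  if (length(drop)) {
    if (missing == "strict") {
      stop("missing trait values for: ", paste(drop, collapse = ", "),
           call. = FALSE)
    }
    if (length(tree$tip.label) - length(drop) < 2L) {
      stop("fewer than 2 leaves with observed states after pruning",
           call. = FALSE)
    }
    tree <- ape::drop.tip(tree, drop)
    x <- x[tree$tip.label]
  }
  list(tree = tree, x = x)
}

#' Marginal ancestral state reconstruction by re-rooting
#'
#' For each internal node the tree is re-rooted at that node
#' ([reroot_at()]), conditional likelihoods are recomputed by pruning under
#' the fitted model, and the marginal posterior is the root-prior-weighted,
#' normalized vector of root conditionals. For the original root this
#' reduces to the normalized prior-weighted root conditionals of the
#' original tree.
#'
#' @param tree The tree the fit was obtained on (pre-pruning trees are
#'   accepted if their observed leaf set matches the fit's).
#' @param tip_states The states the fit was obtained on.
#' @param fit An [fit_mk()] result.
#' @return Object of class `discrete_asr`: a data frame with columns
#'   `node`, `p0`, `p1` (one row per internal node of the analysis tree,
#'   ape node numbering), with the fit attached as attribute `fit`.
#' @export
marginal_asr <- function(tree, tip_states, fit) {
  stopifnot(inherits(fit, "mk_fit"))
  obs <- names(tip_states)[!is.na(tip_states)]
  if (!setequal(intersect(obs, tree$tip.label), fit$tree$tip.label)) {
    stop("tree/fit mismatch: leaf sets differ", call. = FALSE)
  }
  tree <- fit$tree
  x <- fit$tip_states
  model <- fit$model
  ntip <- length(tree$tip.label)
  nodes <- seq.int(ntip + 1L, ntip + tree$Nnode)
  post <- matrix(NA_real_, length(nodes), 2L)
  for (i in seq_along(nodes)) {
    rt <- reroot_at(tree, nodes[i])
    tipL <- .tip_likelihoods(rt, x)
    rc <- .mk_pruning(rt, tipL, model)$root_conditionals
    w <- model$root_prior * rc
    post[i, ] <- w / sum(w)
  }
  out <- data.frame(node = nodes, p0 = post[, 1L], p1 = post[, 2L])
  attr(out, "fit") <- fit
  class(out) <- c("discrete_asr", "data.frame")
  out
}
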