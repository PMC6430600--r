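# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/re-rooting code paths.

# Exhaustive Mk oracle: total likelihood and marginal posteriors by summing
# over every assignment of states to internal nodes (feasible for <= 6
# leaves). Transition probabilities come from numerical matrix
# exponentiation of the rate matrix, not from the package's closed form.
enum_mk_oracle <- function(tree, x, model) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Q <- matrix(c(-model$rates[["q01"]], model$rates[["q01"]],
                model$rates[["q10"]], -model$rates[["q10"]]),
              2, 2, byrow = TRUE)
  Pexp <- function(t) as.matrix(Matrix::expm(Q * t))
  Pe <- lapply(seq_len(nrow(tree$edge)),
               function(k) Pexp(max(tree$edge.length[k], 1e-8)))
  assignments <- as.matrix(expand.grid(rep(list(0:1), nn)))
  tot <- 0
  marg <- matrix(0, nn, 2)
  tipst <- x[tree$tip.label]
  for (r in seq_len(nrow(assignments))) {
    s <- assignments[r, ]
    full <- c(tipst, s)
    p <- unname(model$root_prior[s[1] + 1])
    for (k in seq_len(nrow(tree$edge))) {
      p <- p * Pe[[k]][full[tree$edge[k, 1]] + 1, full[tree$edge[k, 2]] + 1]
    }
    tot <- tot + p
    for (j in seq_len(nn)) marg[j, s[j] + 1] <- marg[j, s[j] + 1] + p
  }
  list(loglik = log(tot), post = marg / tot)
}

# Joint-normal conditional-mean oracle for BM ancestral states: augment the
# tip covariance with ancestral-node covariances (phytools::vcvPhylo) and
# take the conditional expectation given the tips at the GLS root value.
bm_conditional_oracle <- function(tree, x) {
  V <- phytools::vcvPhylo(tree, anc.nodes = TRUE)
  tips <- tree$tip.label
  ntip <- length(tips)
  nodes <- as.character(seq.int(ntip + 2, ntip + tree$Nnode))  # root omitted
  Ct <- V[tips, tips]
  iC <- solve(Ct)
  a <- sum(iC %*% x[tips]) / sum(iC)
  est <- c(stats::setNames(a, ntip + 1),
           if (length(nodes)) {
             Cnt <- V[nodes, tips, drop = FALSE]
             stats::setNames(as.numeric(a + Cnt %*% iC %*% (x[tips] - a)),
                             nodes)
           })
  est
}

# One deterministic nearest-neighbour interchange on a rooted binary tree:
# swap the first child of an eligible internal node with that node's
# sibling subtree. Changes exactly one non-trivial split.
nni_once <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  for (v in seq.int(ntip + 2L, ntip + tree$Nnode)) {
    p <- tree$edge[tree$edge[, 2] == v, 1]
    if (p == root) next
    child_e <- which(tree$edge[, 1] == v)[1]
    sib_e <- which(tree$edge[, 1] == p & tree$edge[, 2] != v)
    tmp <- tree$edge[sib_e, 2]
    tree$edge[sib_e, 2] <- tree$edge[child_e, 2]
    tree$edge[child_e, 2] <- tmp
    return(ape::reorder.phylo(tree, "cladewise"))
  }
  stop("no NNI-eligible edge in this tree")
}

# random binary tip states guaranteed to be polymorphic
random_binary_states <- function(tree) {
  x <- stats::setNames(sample(0:1, length(tree$tip.label), replace = TRUE),
                       tree$tip.label)
  if (length(unique(x)) < 2) x[1] <- 1 - x[1]
  x
}
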