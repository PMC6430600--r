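#' Count non-consensual nodes of a test tree against a reference
#'
#' A non-consensual node is an internal node of the test tree whose
#' bipartition (split) is absent from the reference topology; zero such
#' nodes means the test tree reproduces the reference exactly (for binary
#' trees this equals half the Robinson-Foulds distance). Comparison is on
#' unrooted topologies; both trees are first restricted to their shared
#' leaf set. When the test tree has polytomies only the splits it does
#' resolve are counted against the reference, so unresolved nodes
#' contribute nothing here (see [tree_concordance()] for the separate
#' unresolved count).
#'
#' @param test,reference `phylo` objects.
#' @return Non-negative integer.
#' @export
nonconsensual_count <- function(test, reference) {
  tree_concordance(test, reference)$nonconsensual
}

#' Full concordance report between a test and a reference tree
#'
#' @inheritParams nonconsensual_count
#' @return List with `nonconsensual` (test splits absent from reference),
#'   `unresolved` (reference splits absent from the test tree), and
#'   `shared_leaves`.
#' @export
tree_concordance <- function(test, reference) {
  stopifnot(inherits(test, "phylo"), inherits(reference, "phylo"))
  shared <- intersect(test$tip.label, reference$tip.label)
  if (length(shared) < 4L) {
    stop("leaf-set intersection has fewer than 4 taxa (", length(shared), ")",
         call. = FALSE)
  }
  t1 <- if (length(shared) < length(test$tip.label)) {
    ape::keep.tip(test, shared)
  } else test
  t2 <- if (length(shared) < length(reference$tip.label)) {
    ape::keep.tip(reference, shared)
  } else reference
  s1 <- split_set(t1)
  s2 <- split_set(t2)
  list(
    nonconsensual = length(setdiff(s1, s2)),
    unresolved = length(setdiff(s2, s1)),
    shared_leaves = length(shared)
  )
}

#' Tally phylogenetic markers by error count
#'
#' Groups marker evaluations by their number of non-consensual nodes, the
#' layout used to rank single-gene trees against a multi-gene core
#' phylogeny.
#'
#' @param evals Data frame with columns `marker`, `aligned_positions`
#'   (optional), `non_consensual_nodes`.
#' @return List with `histogram` (named integer vector: error count ->
#'   number of markers) and `markers` (named list: error count -> marker
#'   names). Empty input gives empty components.
#' @export
tally_markers <- function(evals) {
  if (is.null(evals) || !nrow(as.data.frame(evals))) {
    return(list(histogram = integer(0), markers = list()))
  }
  evals <- as.data.frame(evals)
  stopifnot(all(c("marker", "non_consensual_nodes") %in% names(evals)))
  k <- evals$non_consensual_nodes
  stopifnot(all(k >= 0), all(k == round(k)))
  grp <- split(as.character(evals$marker), k)
  hist <- vapply(grp, length, integer(1))
  list(histogram = hist, markers = grp)
}
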