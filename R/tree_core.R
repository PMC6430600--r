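#' Parse a rooted newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Single-quoted labels
#' are accepted (punctuation inside quotes is replaced by underscores, since
#' species names in trait tables are stored with underscores); underscores in
#' unquoted labels are kept verbatim; internal-node support labels are kept
#' as `node.label` and ignored by all downstream computations.
#'
#' @param text A newick string (must end in `;`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' tree_summary(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- .sanitize_quoted_labels(text)
  .check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error: ape could not interpret the string", call. = FALSE)
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  tr
}

# replace "'quoted label'" with a newick-safe token, preserving content
.sanitize_quoted_labels <- function(text) {
  if (!grepl("'", text, fixed = TRUE)) return(text)
  m <- gregexpr("'[^']*'", text)[[1]]
  if (m[1] == -1L) stop("unbalanced single quote in newick string", call. = FALSE)
  out <- text
  for (i in rev(seq_along(m))) {
    start <- m[i]
    len <- attr(m, "match.length")[i]
    lab <- substr(out, start + 1L, start + len - 2L)
    lab <- gsub("[][ (),:;]", "_", lab)
    out <- paste0(substr(out, 1L, start - 1L), lab,
                  substr(out, start + len, nchar(out)))
  }
  out
}

.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at end of string",
         call. = FALSE)
  }
  stripped <- sub("\\s+$", "", text)
  if (!nzchar(stripped) || substr(stripped, nchar(stripped), nchar(stripped)) != ";") {
    stop("newick parse error: missing terminal ';' at position ", nchar(text),
         call. = FALSE)
  }
}

#' Write a tree as newick at full precision
#'
#' Branch lengths are formatted with `%.17g` so that a parse/write/parse
#' round trip reproduces them bit for bit.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to `file`.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  fmt <- function(x) sprintf("%.17g", x)
  rec <- function(node, edge_idx) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      ks <- kids[[as.character(node)]]
      lab <- paste0("(", paste(vapply(ks, function(e) {
        rec(tree$edge[e, 2L], e)
      }, character(1)), collapse = ","), ")")
      nl <- tree$node.label[node - ntip]
      if (!is.null(tree$node.label) && !is.na(nl) && nzchar(nl)) {
        lab <- paste0(lab, nl)
      }
    }
    if (has_len && !is.na(edge_idx)) {
      lab <- paste0(lab, ":", fmt(tree$edge.length[edge_idx]))
    }
    lab
  }
  out <- paste0(rec(root, NA_integer_), ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Clamp zero-length branches
#'
#' Branch lengths of exactly zero break Mk transition matrices and make the
#' Brownian covariance singular; they are clamped to a small positive
#' epsilon before any likelihood computation.
#'
#' @param tree A `phylo` object.
#' @param eps Lower bound applied to branch lengths (default `1e-8`).
#' @return The tree with `edge.length >= eps`.
#' @export
clamp_branch_lengths <- function(tree, eps = 1e-8) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  tree$edge.length <- pmax(tree$edge.length, eps)
  tree
}

#' Re-root a tree at an internal node
#'
#' The tree is first unrooted (a degree-2 root is spliced out, its two
#' incident branch lengths summed) and then re-rooted with `node` as the new
#' root, which therefore becomes a basal multifurcation. The unrooted
#' topology and every leaf-to-leaf path length are unchanged. This is the
#' core primitive of marginal ancestral state reconstruction by the
#' re-rooting method.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param node Internal node id (ape numbering: `Ntip + 1 ...`).
#' @return A `phylo` object rooted at `node`, with an attribute `node_map`,
#'   a named integer vector mapping original node ids to ids in the
#'   re-rooted tree (the spliced-out original root, if any, maps to `NA`).
#' @export
reroot_at <- function(tree, node) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode_all <- ntip + tree$Nnode
  if (!is.numeric(node) || length(node) != 1L || node != round(node) ||
      node < 1L || node > nnode_all) {
    stop("node ", node, " is not a node of the tree", call. = FALSE)
  }
  node <- as.integer(node)
  if (node <= ntip) stop("cannot re-root at a leaf", call. = FALSE)
  root_old <- ntip + 1L
  if (node == root_old) {
    map <- seq_len(nnode_all)
    names(map) <- as.character(map)
    attr(tree, "node_map") <- map
    return(tree)
  }
  has_len <- !is.null(tree$edge.length)
  if (!has_len) tree$edge.length <- rep(1, nrow(tree$edge))

  # undirected adjacency: parallel vectors of (from, to, length)
  a <- c(tree$edge[, 1L], tree$edge[, 2L])
  b <- c(tree$edge[, 2L], tree$edge[, 1L])
  w <- c(tree$edge.length, tree$edge.length)
  nbr <- split(seq_along(a), a)
  deg <- lengths(nbr)

  removed <- NA_integer_
  if (deg[[as.character(root_old)]] == 2L) {
    # splice the old degree-2 root out of the graph
    idx <- nbr[[as.character(root_old)]]
    n1 <- b[idx[1L]]; n2 <- b[idx[2L]]
    wsum <- w[idx[1L]] + w[idx[2L]]
    keep <- a != root_old & b != root_old
    a <- c(a[keep], n1, n2)
    b <- c(b[keep], n2, n1)
    w <- c(w[keep], wsum, wsum)
    nbr <- split(seq_along(a), a)
    removed <- root_old
  }

  # iterative DFS from the new root, building a child edge list
  parent <- integer(0); child <- integer(0); len <- numeric(0)
  visited <- rep(FALSE, nnode_all)
  stack <- node
  visited[node] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    idx <- nbr[[as.character(v)]]
    for (e in idx) {
      u <- b[e]
      if (!visited[u]) {
        visited[u] <- TRUE
        parent <- c(parent, v); child <- c(child, u); len <- c(len, w[e])
        stack <- c(stack, u)
      }
    }
  }

  # renumber: tips keep ids 1..ntip; internals in preorder, root first
  internals_old <- c(node, setdiff(unique(parent), node))
  # preorder: order internals by first appearance as parent
  first_seen <- match(internals_old, parent)
  internals_old <- internals_old[order(first_seen)]
  new_id <- integer(nnode_all)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[internals_old] <- ntip + seq_along(internals_old)

  edge <- cbind(new_id[parent], new_id[child])
  o <- order(edge[, 1L], edge[, 2L])
  out <- list(
    edge = edge[o, , drop = FALSE],
    edge.length = len[o],
    tip.label = tree$tip.label,
    Nnode = length(internals_old)
  )
  if (!is.null(tree$node.label)) {
    nl <- character(length(internals_old))
    nl[new_id[internals_old] - ntip] <- tree$node.label[internals_old - ntip]
    out$node.label <- nl
  }
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  if (!has_len) out$edge.length <- NULL

  map <- rep(NA_integer_, nnode_all)
  map[visited] <- new_id[visited]
  if (!is.na(removed)) map[removed] <- NA_integer_
  names(map) <- as.character(seq_len(nnode_all))
  attr(out, "node_map") <- map
  out
}

#' Non-trivial splits (bipartitions) of a tree
#'
#' One split per internal edge of the unrooted version of the tree; trivial
#' splits (one leaf versus the rest) are excluded. Splits are returned as
#' canonical string keys — the block of leaf labels *not* containing the
#' alphabetically first leaf, sorted and joined — so split sets from two
#' trees on the same leaf set are directly comparable. For a fully binary
#' unrooted tree on `n` leaves the set has `n - 3` elements.
#'
#' @param tree A `phylo` object (rooted or unrooted; polytomies allowed).
#' @return Character vector of canonical split keys (possibly empty), with
#'   attribute `leaves` giving the sorted leaf label set.
#' @export
split_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  leaves <- sort(tree$tip.label)
  if (ntip < 4L) {
    out <- character(0)
    attr(out, "leaves") <- leaves
    return(out)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  nnode_all <- ntip + tree$Nnode
  desc <- vector("list", nnode_all)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- leaves[1L]
  keys <- character(0)
  root <- ntip + 1L
  for (v in setdiff(seq.int(ntip + 1L, nnode_all), root)) {
    blk <- desc[[v]]
    if (ref %in% blk) blk <- setdiff(leaves, blk)
    if (length(blk) < 2L || length(blk) > ntip - 2L) next
    keys <- c(keys, paste(sort(blk), collapse = "\r"))
  }
  out <- sort(unique(keys))
  attr(out, "leaves") <- leaves
  out
}

#' Summarize a tree
#'
#' @param tree A `phylo` object.
#' @return List with `leaves`, `internal_nodes`, `total_length`.
#' @export
tree_summary <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  list(
    leaves = length(tree$tip.label),
    internal_nodes = tree$Nnode,
    total_length = if (is.null(tree$edge.length)) NA_real_ else sum(tree$edge.length)
  )
}

# strictly binary rooted tree check used by the ASR modules
.assert_binary_rooted <- function(tree, what = "this analysis") {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop(what, " requires a rooted tree", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    stop(what, " requires a strictly binary tree (resolve polytomies first)",
         call. = FALSE)
  }
  invisible(tree)
}
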