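# run code with a locally set RNG seed, restoring global RNG state after;
# seed = NULL means "use the current RNG stream" (for nested calls)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Rooted, binary, ultrametric tree on `n` leaves via [ape::rphylo()] with
#' zero death rate. Reproducible under `seed` without disturbing the
#' caller's RNG state.
#'
#' @param n Number of leaves (`>= 2`).
#' @param birth_rate Speciation rate (default 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param tip_prefix Prefix for tip labels.
#' @return A `phylo` object with tips `<tip_prefix>1 ... <tip_prefix>n`.
#' @export
simulate_yule <- function(n, birth_rate = 1, seed = NULL, tip_prefix = "t") {
  if (!is.numeric(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  tr <- .with_seed(seed, ape::rphylo(n, birth = birth_rate, death = 0))
  tr$tip.label <- paste0(tip_prefix, seq_len(n))
  tr
}

#' Rescale branch lengths within named clades
#'
#' Multiplies the branch lengths inside each clade (all edges below the
#' clade's most recent common ancestor, and optionally its stem edge) by a
#' factor, leaving the topology unchanged. This is how a rate-heterogeneous
#' rival tree (very short branches inside one group, a long stem to
#' another) is produced from a uniform-rate tree.
#'
#' @param tree A rooted `phylo`.
#' @param clade_scalers List of specs, each a list with elements `tips`
#'   (leaf labels forming a clade), `factor` (positive multiplier), and
#'   optional `stem` (logical, default `FALSE`: also scale the clade's stem
#'   edge).
#' @return The rescaled tree.
#' @export
distort_branch_lengths <- function(tree, clade_scalers) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  for (spec in clade_scalers) {
    tips <- spec$tips
    fac <- spec$factor
    stem <- isTRUE(spec$stem)
    stopifnot(is.numeric(fac), fac > 0)
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss)) stop("unknown tips: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    if (length(tips) == 1L) {
      node <- match(tips, tree$tip.label)
      inside <- integer(0)
    } else {
      node <- ape::getMRCA(tree, tips)
      desc <- ape::extract.clade(tree, node)$tip.label
      if (!setequal(desc, tips)) {
        stop("leaf set {", paste(tips, collapse = ", "),
             "} is not a clade of the tree", call. = FALSE)
      }
      # edges wholly inside the clade: parent in the subtree rooted at node
      sub_nodes <- node
      repeat {
        more <- tree$edge[tree$edge[, 1L] %in% sub_nodes, 2L]
        more <- more[more > ntip & !(more %in% sub_nodes)]
        if (!length(more)) break
        sub_nodes <- c(sub_nodes, more)
      }
      inside <- which(tree$edge[, 1L] %in% sub_nodes)
    }
    tree$edge.length[inside] <- tree$edge.length[inside] * fac
    if (stem) {
      st <- which(tree$edge[, 2L] == node)
      tree$edge.length[st] <- tree$edge.length[st] * fac
    }
  }
  tree
}

#' Simulate a binary trait under the Mk model
#'
#' Evolves a two-state character root-to-tip; along a branch of length `t`
#' the state flips with probability `(1 - exp(-2 q t)) / 2` (the symmetric
#' two-state chain).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param q Transition rate (`>= 0`).
#' @param root_state 0 or 1 at the root.
#' @param seed Optional seed (see [simulate_yule()]).
#' @return Named 0/1 vector over the tips.
#' @export
simulate_mk_trait <- function(tree, q, root_state = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), q >= 0, root_state %in% c(0, 1))
  .with_seed(seed, {
    ntip <- length(tree$tip.label)
    st <- integer(ntip + tree$Nnode)
    st[ntip + 1L] <- root_state
    pre <- ape::reorder.phylo(tree, "cladewise")
    pflip <- 0.5 * (1 - exp(-2 * q * pre$edge.length))
    flip <- stats::runif(nrow(pre$edge)) < pflip
    for (k in seq_len(nrow(pre$edge))) {
      ch <- pre$edge[k, 2L]
      st[ch] <- if (flip[k]) 1L - st[pre$edge[k, 1L]] else st[pre$edge[k, 1L]]
    }
    stats::setNames(st[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate a continuous trait under Brownian motion
#'
#' Independent normal increments per branch with variance `sigma2 * t`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma2 Brownian rate (`>= 0`), squared trait units per unit
#'   branch length.
#' @param root_value Trait value at the root.
#' @param seed Optional seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm_trait <- function(tree, sigma2, root_value = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), sigma2 >= 0)
  .with_seed(seed, {
    ntip <- length(tree$tip.label)
    val <- numeric(ntip + tree$Nnode)
    val[ntip + 1L] <- root_value
    pre <- ape::reorder.phylo(tree, "cladewise")
    inc <- stats::rnorm(nrow(pre$edge), 0, sqrt(sigma2 * pre$edge.length))
    for (k in seq_len(nrow(pre$edge))) {
      val[pre$edge[k, 2L]] <- val[pre$edge[k, 1L]] + inc[k]
    }
    stats::setNames(val[seq_len(ntip)], tree$tip.label)
  })
}

#' Generate a complete study-shaped fixture bundle
#'
#' Emulates the shape of the Dictyostelia arbitration inputs with no real
#' data: a 52-taxon (+3 outgroup) rooted binary tree in two rival versions
#' over the same leaf set — `tree_a` with roughly uniform, ultrametric
#' branch lengths and `tree_b` with strong rate heterogeneity (group-4
#' internal branches shortened 50-fold, the other groups' branches
#' lengthened, a long stem to group 1) — plus 13 binary traits (the first
#' is a "stalk-support-like" focal trait that evolves, labile, only within
#' group 4; the next two are clade indicators for group 4 and group 1; the
#' rest evolve under Mk), 12 continuous Brownian traits (the first
#' three carry a
#' group-4 mean shift), and six nucleotide fragment alignments totalling
#' 2711 columns with per-clade G/C targets spanning 0.27-0.61 (one group-4
#' exemplar at the low extreme, one group-2 exemplar at the high extreme).
#' A fixed seed makes the bundle byte-identical across runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; recorded in the header of every text output.
#' @param group_sizes Named sizes of the four major groups.
#' @param n_outgroup Number of outgroup taxa.
#' @param n_discrete,n_continuous Trait counts.
#' @param mk_rate Mk rate for the simulated discrete traits.
#' @param bm_sigma2 Brownian rate for the continuous traits.
#' @param missing_fraction Fraction of trait cells (simulated traits only)
#'   and of (taxon, fragment) pairs set to missing.
#' @param gc_targets Named per-group G/C targets plus `low`/`high`
#'   exemplar overrides.
#' @param fragment_lengths Lengths of the six fragments (sum 2711).
#' @return Invisibly, a list with the generated objects (`tree_a`,
#'   `tree_b`, `traits`, `rules`, `fragments`, `groups`) and `paths` to the
#'   written files.
#' @export
make_study_fixture <- function(out_dir, seed = 1,
                               group_sizes = c(G1 = 3, G2 = 6, G3 = 12, G4 = 31),
                               n_outgroup = 3,
                               n_discrete = 13, n_continuous = 12,
                               mk_rate = 0.5, bm_sigma2 = 1,
                               missing_fraction = 0.05,
                               gc_targets = c(OUT = 0.45, G1 = 0.52, G2 = 0.58,
                                              G3 = 0.42, G4 = 0.32,
                                              low = 0.27, high = 0.61),
                               fragment_lengths = c(452, 430, 478, 455, 405, 491)) {
  stopifnot(sum(group_sizes) + n_outgroup >= 8, n_discrete >= 3,
            n_continuous >= 3)
  dir.create(file.path(out_dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  .with_seed(seed, {
    ## trees -------------------------------------------------------------
    grp_tr <- lapply(names(group_sizes), function(g) {
      tr <- simulate_yule(group_sizes[[g]], tip_prefix = sprintf("%s_sp", g))
      tr$tip.label <- sprintf("%s_sp%02d", g, seq_len(group_sizes[[g]]))
      .rescale_depth(tr, 0.5)
    })
    names(grp_tr) <- names(group_sizes)
    out_tr <- simulate_yule(n_outgroup, tip_prefix = "OUT_sp")
    out_tr$tip.label <- sprintf("OUT_sp%02d", seq_len(n_outgroup))
    out_tr <- .rescale_depth(out_tr, 0.3)
    stemmed <- function(tr, stem) paste0(sub(";$", "", write_newick(tr)), ":",
                                         sprintf("%.17g", stem))
    # ultrametric skeleton: groups join pairwise at 0.8, branches at 1.0,
    # outgroup at 1.3
    ingroup <- paste0(
      "((", stemmed(grp_tr$G1, 0.3), ",", stemmed(grp_tr$G2, 0.3), "):0.2,",
      "(", stemmed(grp_tr$G3, 0.3), ",", stemmed(grp_tr$G4, 0.3), "):0.2):0.3"
    )
    tree_a <- parse_newick(paste0("(", ingroup, ",", stemmed(out_tr, 1.0), ");"))
    groups <- c(names(group_sizes), "OUT")
    membership <- stats::setNames(sub("_sp.*$", "", tree_a$tip.label),
                                  tree_a$tip.label)
    tipset <- function(g) names(membership)[membership == g]
    tree_b <- distort_branch_lengths(tree_a, list(
      list(tips = tipset("G1"), factor = 5, stem = TRUE),
      list(tips = tipset("G2"), factor = 2, stem = TRUE),
      list(tips = tipset("G3"), factor = 2, stem = TRUE),
      list(tips = tipset("G4"), factor = 0.02, stem = FALSE)
    ))

    ## traits ------------------------------------------------------------
    taxa <- tree_a$tip.label
    yesno <- function(v) ifelse(v == 1, "yes", "no")
    disc <- matrix(NA_character_, length(taxa), n_discrete,
                   dimnames = list(taxa, sprintf("d%02d", seq_len(n_discrete))))
    # d01 is the "stalk-support-like" focal trait: it evolves only within
    # group 4, and is labile there (several gains and losses, the lability
    # the published per-trait log-likelihoods imply). Its changes therefore
    # all sit on group-4-internal branches — the branch class the
    # heterogeneous rival tree shortens 50-fold. Target ~8 changes over the
    # group-4 subtree; resample (bounded) until the realized pattern shows
    # at least 6 parsimony changes and both states are well represented.
    g4_mrca <- ape::getMRCA(tree_a, tipset("G4"))
    g4_tree <- ape::extract.clade(tree_a, g4_mrca)
    q_focal <- 8 / sum(g4_tree$edge.length)
    focal <- NULL
    for (try in seq_len(50L)) {
      y <- simulate_mk_trait(g4_tree, q_focal, root_state = 0)
      full <- stats::setNames(integer(length(taxa)), taxa)
      full[names(y)] <- y
      if (sum(y) >= 6 && sum(1 - y) >= 6 &&
          .fitch_changes(tree_a, full) >= 6) { focal <- full; break }
    }
    if (is.null(focal)) focal <- full
    disc[, 1L] <- yesno(focal[taxa])
    disc[, 2L] <- yesno(as.integer(membership == "G4"))
    disc[, 3L] <- yesno(as.integer(membership == "G1"))
    for (j in seq_len(n_discrete)[-(1:3)]) {
      disc[, j] <- yesno(simulate_mk_trait(tree_a, mk_rate)[taxa])
    }
    cont <- matrix(NA_real_, length(taxa), n_continuous,
                   dimnames = list(taxa, sprintf("c%02d", seq_len(n_continuous))))
    for (j in seq_len(n_continuous)) {
      v <- simulate_bm_trait(tree_a, bm_sigma2)[taxa]
      if (j <= 3L) v <- v + 3 * (membership == "G4")
      cont[, j] <- v
    }
    # missing data only in the simulated (non-indicator) traits
    for (j in seq_len(n_discrete)[-(1:3)]) {
      disc[stats::runif(length(taxa)) < missing_fraction, j] <- NA
    }
    for (j in seq_len(n_continuous)[-(1:3)]) {
      cont[stats::runif(length(taxa)) < missing_fraction, j] <- NA
    }
    traits <- data.frame(taxon = taxa, disc, cont, check.names = FALSE,
                         stringsAsFactors = FALSE)
    rules <- list(
      discrete = stats::setNames(
        rep(list(list(yes = 1, no = 0)), n_discrete), colnames(disc)),
      continuous = as.list(colnames(cont))
    )

    ## sequence fragments -------------------------------------------------
    gc_of <- gc_targets[membership]
    names(gc_of) <- names(membership)
    gc_of["G4_sp01"] <- gc_targets[["low"]]
    gc_of["G2_sp01"] <- gc_targets[["high"]]
    exemplars <- c("G4_sp01", "G2_sp01")
    fragments <- vector("list", length(fragment_lengths))
    for (f in seq_along(fragment_lengths)) {
      w <- fragment_lengths[f]
      have <- taxa[taxa %in% exemplars |
                     stats::runif(length(taxa)) >= missing_fraction]
      seqs <- vapply(have, function(tx) {
        p <- gc_of[[tx]]
        paste(sample(c("G", "C", "A", "T"), w, replace = TRUE,
                     prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
              collapse = "")
      }, character(1))
      fragments[[f]] <- alignment(seqs, name = sprintf("frag%d", f))
    }

    ## write --------------------------------------------------------------
    paths <- list(
      tree_a = file.path(out_dir, "treeA.nwk"),
      tree_b = file.path(out_dir, "treeB.nwk"),
      traits = file.path(out_dir, "traits.tsv"),
      rules = file.path(out_dir, "rules.yaml"),
      fragments = file.path(out_dir, "fragments",
                            sprintf("frag%d.fasta", seq_along(fragments)))
    )
    write_newick(tree_a, paths$tree_a)
    write_newick(tree_b, paths$tree_b)
    con <- file(paths$traits, "w")
    writeLines(sprintf("# study-shaped synthetic traits; seed: %d", seed), con)
    utils::write.table(traits, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    writeLines(c(sprintf("# binarization rules; seed: %d", seed),
                 yaml::as.yaml(rules)), paths$rules)
    for (f in seq_along(fragments)) {
      write_alignment(fragments[[f]], paths$fragments[f])
    }
    invisible(list(tree_a = tree_a, tree_b = tree_b, traits = traits,
                   rules = rules, fragments = fragments,
                   groups = membership, paths = paths, seed = seed))
  })
}

# Fitch parsimony change count of a binary character on a binary tree
.fitch_changes <- function(tree, x) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0, 1}
  S <- integer(ntip + tree$Nnode)
  S[seq_len(ntip)] <- ifelse(x[tree$tip.label] == 0, 1L, 2L)
  changes <- 0L
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    if (S[p] == 0L) {
      S[p] <- S[ch]
    } else if (bitwAnd(S[p], S[ch]) > 0L) {
      S[p] <- bitwAnd(S[p], S[ch])
    } else {
      S[p] <- bitwOr(S[p], S[ch])
      changes <- changes + 1L
    }
  }
  changes
}

# rescale an ultrametric tree to a fixed root-to-tip depth
.rescale_depth <- function(tree, depth) {
  d <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (depth / d)
  tree
}
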