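#' Read a run configuration
#'
#' Flat YAML with fail-fast validation: unknown keys are errors, and every
#' referenced path must exist. Defaults are filled for all optional keys.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("tree_a", "tree_b", "traits", "rules", "out_dir",
             "model_class", "root_prior", "tie_tol", "log10_traits",
             "seed", "marker_dir", "reference_tree")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(model_class = "ER", root_prior = "flat", tie_tol = 1e-6,
                   log10_traits = character(0), seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("tree_a", "tree_b", "traits", "rules", "marker_dir",
              "reference_tree")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("config path does not exist: ", k, " = ", cfg[[k]], call. = FALSE)
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a newick tree from a file
#'
#' @param path File containing one newick tree.
#' @return A `phylo` object (validated by [parse_newick()]).
#' @export
read_tree_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Read a trait table
#'
#' Tab-separated, `#` comment lines allowed, first column `taxon`.
#'
#' @param path TSV path.
#' @return Data frame with taxa as rows.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "taxon") {
    stop("trait table must have 'taxon' as its first column", call. = FALSE)
  }
  if (anyDuplicated(df$taxon)) stop("duplicate taxa in trait table",
                                    call. = FALSE)
  df
}

#' Run the full two-tree validity analysis
#'
#' For every discrete trait (binarized by the configured rules) the Mk
#' model is fitted on both trees and the root marginal log-likelihoods are
#' compared; for every continuous trait, Brownian-motion reconstructions
#' are compared by mean node variance. Writes a per-trait report TSV, a
#' JSON summary (favoured counts, mean advantages, mean variance ratio),
#' per-trait per-node ASR tables, and a run log recording model choices
#' and pruned taxa. Outputs carry the seed and a hash of the configuration
#' so identical configurations yield byte-identical files.
#'
#' @param config A [read_run_config()] result, path, or named list with at
#'   least `tree_a`, `tree_b`, `traits`, `rules`, `out_dir`.
#' @return Invisibly, a list with `report` (data frame), `summary` (list),
#'   and `paths`.
#' @export
run_validity <- function(config) {
  cfg <- read_run_config(config)
  for (k in c("tree_a", "tree_b", "traits", "rules", "out_dir")) {
    if (is.null(cfg[[k]])) stop("config key required: ", k, call. = FALSE)
  }
  dir.create(file.path(cfg$out_dir, "asr"), recursive = TRUE,
             showWarnings = FALSE)
  log_lines <- c(sprintf("run_validity seed=%s model=%s root_prior=%s",
                         cfg$seed, cfg$model_class, cfg$root_prior))
  tree_a <- read_tree_file(cfg$tree_a)
  tree_b <- read_tree_file(cfg$tree_b)
  mism <- c(setdiff(tree_a$tip.label, tree_b$tip.label),
            setdiff(tree_b$tip.label, tree_a$tip.label))
  if (length(mism)) {
    stop("trees disagree on taxa: ", paste(mism, collapse = ", "),
         call. = FALSE)
  }
  traits <- read_trait_table(cfg$traits)
  rules <- .read_rules(cfg$rules)
  extra <- setdiff(traits$taxon, tree_a$tip.label)
  if (length(extra)) {
    stop("trait table taxa absent from the trees: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }

  rows <- list()
  for (tr in names(rules$discrete)) {
    x <- binarize(stats::setNames(traits[[tr]], traits$taxon),
                  rules$discrete[[tr]])
    cd <- compare_discrete(tree_a, tree_b, x, model_class = cfg$model_class,
                           root_prior = cfg$root_prior, tie_tol = cfg$tie_tol)
    dropped <- setdiff(tree_a$tip.label, cd$fit_a$tree$tip.label)
    if (length(dropped)) {
      log_lines <- c(log_lines, sprintf("%s: pruned %s", tr,
                                        paste(dropped, collapse = ",")))
    }
    .write_asr_tsv(marginal_asr(cd$fit_a$tree, cd$fit_a$tip_states, cd$fit_a),
                   file.path(cfg$out_dir, "asr", paste0(tr, "_treeA.tsv")))
    .write_asr_tsv(marginal_asr(cd$fit_b$tree, cd$fit_b$tip_states, cd$fit_b),
                   file.path(cfg$out_dir, "asr", paste0(tr, "_treeB.tsv")))
    rows[[tr]] <- data.frame(
      trait = tr, type = "discrete", n_taxa = cd$n_taxa,
      loglik_a = cd$loglik_a, loglik_b = cd$loglik_b,
      favoured = cd$favoured, mean_var_a = NA_real_, mean_var_b = NA_real_,
      ratio = NA_real_, stringsAsFactors = FALSE)
  }
  for (tr in unlist(rules$continuous)) {
    x <- stats::setNames(as.numeric(traits[[tr]]), traits$taxon)
    cc <- compare_continuous(tree_a, tree_b, x,
                             log10_transform = tr %in% cfg$log10_traits)
    .write_asr_tsv(cc$asr_a,
                   file.path(cfg$out_dir, "asr", paste0(tr, "_treeA.tsv")))
    .write_asr_tsv(cc$asr_b,
                   file.path(cfg$out_dir, "asr", paste0(tr, "_treeB.tsv")))
    rows[[tr]] <- data.frame(
      trait = tr, type = "continuous", n_taxa = cc$n_taxa,
      loglik_a = NA_real_, loglik_b = NA_real_, favoured = NA_character_,
      mean_var_a = cc$mean_var_a, mean_var_b = cc$mean_var_b,
      ratio = cc$ratio, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  d <- report[report$type == "discrete", ]
  cc <- report[report$type == "continuous", ]
  summ <- summarize_validity(discrete = d, continuous = cc,
                             tie_tol = cfg$tie_tol)

  paths <- list(report = file.path(cfg$out_dir, "validity_report.tsv"),
                summary = file.path(cfg$out_dir, "summary.json"),
                log = file.path(cfg$out_dir, "run.log"))
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  con <- file(paths$report, "w")
  writeLines(sprintf("# validity report; seed: %s; config: %s",
                     cfg$seed, cfg_hash), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = cfg$seed, summary = summ),
    paths$summary, auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
  writeLines(log_lines, paths$log)
  invisible(list(report = report, summary = summ, paths = paths))
}

.read_rules <- function(path) {
  rules <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(rules), !is.null(rules$discrete) || !is.null(rules$continuous))
  rules
}

.write_asr_tsv <- function(asr, path) {
  df <- as.data.frame(asr)
  utils::write.table(format(df, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate a directory of single-marker trees against a reference
#'
#' Each readable newick file in `marker_dir` is compared to the reference
#' topology by [tree_concordance()]; unreadable files are logged and
#' skipped. Writes a per-marker TSV and a JSON tally (markers grouped by
#' non-consensual node count).
#'
#' @param config A config (path or list) with `marker_dir`,
#'   `reference_tree`, `out_dir`.
#' @return Invisibly, a list with `evals` (data frame), `tally`,
#'   `n_skipped`, and `paths`.
#' @export
run_marker_eval <- function(config) {
  cfg <- read_run_config(config)
  for (k in c("marker_dir", "reference_tree", "out_dir")) {
    if (is.null(cfg[[k]])) stop("config key required: ", k, call. = FALSE)
  }
  files <- list.files(cfg$marker_dir, pattern = "\\.(nwk|newick|tree|tre)$",
                      full.names = TRUE)
  if (!length(files)) stop("no marker trees found in ", cfg$marker_dir,
                           call. = FALSE)
  reference <- read_tree_file(cfg$reference_tree)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  skipped <- character(0)
  for (f in files) {
    marker <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      tc <- tree_concordance(read_tree_file(f), reference)
      data.frame(marker = marker, non_consensual_nodes = tc$nonconsensual,
                 unresolved = tc$unresolved, shared_leaves = tc$shared_leaves,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      skipped <<- c(skipped, sprintf("%s: %s", marker, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[marker]] <- res
  }
  if (!length(rows)) stop("no marker tree could be evaluated", call. = FALSE)
  evals <- do.call(rbind, rows)
  rownames(evals) <- NULL
  tl <- tally_markers(evals)
  paths <- list(evals = file.path(cfg$out_dir, "marker_eval.tsv"),
                tally = file.path(cfg$out_dir, "marker_tally.json"),
                log = file.path(cfg$out_dir, "marker_eval.log"))
  con <- file(paths$evals, "w")
  writeLines(sprintf("# marker evaluation; seed: %s", cfg$seed), con)
  utils::write.table(evals, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(seed = cfg$seed, histogram = as.list(tl$histogram),
         markers = tl$markers, n_skipped = length(skipped)),
    paths$tally, auto_unbox = TRUE, pretty = TRUE)
  writeLines(c(sprintf("evaluated %d marker(s), skipped %d",
                       nrow(evals), length(skipped)), skipped), paths$log)
  invisible(list(evals = evals, tally = tl, n_skipped = length(skipped),
                 paths = paths))
}
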