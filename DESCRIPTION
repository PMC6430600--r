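Package: phyloarb
Title: Trait-Based Arbitration Between Rival Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding which of two competing phylogenies of the
    same species better explains a set of phenotypic traits. Binary traits
    are fitted with the two-state Mk model and reconstructed by marginal
    (re-rooting) ancestral state estimation; continuous traits are
    reconstructed under Brownian motion with per-node variances and 95%
    confidence intervals. Goodness-of-fit statistics (root marginal
    log-likelihood, mean node variance ratio) summarize which tree is
    favoured per trait. Also included: bipartition-based counting of
    non-consensual nodes for phylogenetic-marker validation, alignment
    concatenation and column filtering, per-taxon G/C content, and seeded
    generators of study-shaped synthetic data (rival trees, Mk and
    Brownian traits, coding-sequence fragments).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
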