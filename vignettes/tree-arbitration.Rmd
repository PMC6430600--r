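---
title: "Arbitrating between rival phylogenies with trait reconstructions"
author: "phyloarb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating between rival phylogenies with trait reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloarb)
```

## The question this package answers

Two phylogenies of the same species — in the motivating system, a
six-protein supermatrix tree and a single-marker SSU rDNA tree of 55
dictyostelid taxa — cannot both be right. Tree inference itself (Bayesian
or ML, from sequence supermatrices) is out of scope here; phyloarb starts
where that ends, with two candidate trees in hand, and asks which tree the
*phenotypes* prefer. The logic: reconstruct each trait's ancestral history
on both trees; the tree under which the histories are more likely (binary
traits) or more confidently estimated (continuous traits) is the better
working hypothesis for comparative biology.

## Models and procedure

### Binary traits: the two-state Mk model

A binary character evolves along each branch as a continuous-time Markov
chain with rates $q_{01}, q_{10}$ per unit branch length. The transition
matrix over a branch of length $t$ has the closed form
$P(t) = \Pi + e^{-(q_{01}+q_{10})t}(I - \Pi)$, with $\Pi$ the stationary
distribution in each row; under equal rates (ER, the default)
$P(\text{stay}) = \tfrac12(1 + e^{-2qt})$. Tip data likelihoods are
computed by Felsenstein's pruning algorithm — a post-order dynamic program
over per-node conditional likelihood vectors — with per-edge rescaling so
that 55-taxon trees do not underflow. A root prior $\pi$ (flat by default)
weights the root conditionals; the resulting total log-likelihood is the
"marginal likelihood at the root" used as the per-trait goodness-of-fit
score.

Marginal ancestral states use the re-rooting method: the marginal posterior
at internal node $v$ equals the normalized $\pi$-weighted root conditionals
of the tree re-rooted at $v$. `reroot_at()` implements the re-rooting
from scratch on an adjacency representation (the old degree-2 root is
spliced out; node identity is tracked across the operation), and
`marginal_asr()` literally re-roots at every internal node. For the
symmetric ER model this is exactly equivalent to marginalizing over all
internal states, which the test suite verifies by brute-force enumeration
on all trees with up to six leaves.

### Continuous traits: Brownian motion

Under Brownian motion with rate $\sigma^2$, tip values are jointly normal
with covariance $\sigma^2 C$, where $C_{ij}$ is the shared root-to-tip path
length. The root state is the GLS estimate
$\hat a = (\mathbf 1^\top C^{-1}\mathbf 1)^{-1}\mathbf 1^\top C^{-1} x$ and
$\hat\sigma^2 = (x-\hat a\mathbf 1)^\top C^{-1}(x-\hat a\mathbf 1)/n$ (ML,
i.e. divided by $n$; the classical contrasts estimator divides by $n-1$,
and the suite checks that the two differ by exactly that factor against an
independent implementation). The estimate at any internal node is the GLS
root value of the re-rooted tree; its variance is
$\hat\sigma^2 (\mathbf 1^\top C_v^{-1}\mathbf 1)^{-1}$, conditioning on
$\hat\sigma^2$ (no rate uncertainty is propagated — the variances are used
as a *relative* score between trees, not as calibrated uncertainty). The
95% CI multiplier is fixed at 1.959964. The per-trait score is the
arithmetic mean of the node variances; `variance_ratio()` compares trees.

### The arbitration summary

`compare_discrete()` and `compare_continuous()` prune both trees to the
same per-trait observed taxon set before fitting — likelihoods computed on
different data are not commensurable — and re-fit all parameters per tree.
`summarize_validity()` then counts traits favouring each tree (ties, at
absolute log-likelihood differences below `tie_tol = 1e-6`, count for
neither side and are excluded from the mean-advantage denominators) and
averages the continuous variance ratios.

### Marker validation

`nonconsensual_count()` operationalizes "non-consensual node" as a
non-trivial bipartition of the test tree absent from the reference
topology, compared unrooted on the shared leaf set. For binary trees this
equals half the Robinson–Foulds distance (cross-checked against phangorn
on hundreds of random pairs). When a test tree is incompletely resolved,
its polytomies are not counted as errors; the reference splits it fails to
resolve are reported separately as `unresolved`, mirroring how marker
surveys annotate resolution separately from conflict.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `model_class` | `"ER"` | ER or ARD | One rate is the parsimonious default for 13 binary traits on ≤ 55 taxa; ARD is available but doubles the parameters. |
| `root_prior` | `"flat"` | (½, ½), stationary, or custom | Flat matches the root-marginal-likelihood reading of the fit score. |
| rate search | log *q* ∈ [ln 10⁻⁶, ln 10³] | per unit branch length | Brackets everything from effectively-frozen to saturation; fits at (or on plateaus reaching) the bounds carry `boundary = TRUE`. |
| `tie_tol` | 10⁻⁶ | log-likelihood | Self-comparisons must report ties, not noise-driven winners. |
| branch-length clamp | 10⁻⁸ | branch-length units | Zero lengths break $P(t)$ and make $C$ singular; the clamp is far below any biological signal. |
| `missing` | `"prune"` | prune / strict | Trait tables from PCR surveys have gaps; pruning per trait is the standard comparative-methods choice. |
| `log10_transform` | off | per trait | Traits are analyzed on the scale given; a log10 option exists for dimension-like traits because no transform is prescribed by the workflow itself. |
| `ci95` multiplier | 1.959964 | — | Normal-theory interval, fixed for reproducibility. |

## The synthetic-data generator

`make_study_fixture()` emulates the *shape* of the motivating inputs, not
their content: 52 ingroup taxa in four groups (3, 6, 12, 31 — group 4
largest, mirroring the real sampling emphasis) plus 3 outgroup taxa; an
ultrametric "uniform" tree assembled from seeded Yule subtrees; and a
rival tree with the same topology whose branch lengths are distorted the
way SSU rDNA rates are distorted — every branch inside group 4 shortened
50-fold (factor 0.02), groups 1–3 lengthened (factors 5, 2, 2, with
stems — group 1 gets the long stem). Thirteen binary and twelve continuous
traits carry clade-structured signal; six nucleotide fragments (lengths
summing to 2711 columns, the length of the real concatenated PCR
supermatrix) have per-group G/C targets spanning 0.27–0.61, with one
group-4 exemplar taxon at the 0.27 extreme and one group-2 exemplar at
0.61.

The focal binary trait deserves its own paragraph, because it drives the
package's key qualitative reproduction. A trait confined to group 4 whose
single origin sits on the group-4 stem is *uninformative* about branch-length
pathology: its one required change is cheap on either tree. The diagnostic
phenotype is a *labile* trait — several gains and losses, all inside group
4. On the uniform tree those changes sit on ordinary branches and the
fitted rate stays moderate, so deep nodes outside group 4 are confidently
reconstructed as lacking the trait. On the rate-heterogeneous tree the
same changes are forced onto 50-fold-shortened branches; the only way the
Mk likelihood can pay for them is a very large rate, and at that rate the
transition probabilities across the long deep branches saturate toward ½ —
the trait is "assigned with 50% probability" at the last common ancestors
of groups 1–3. The generator therefore simulates the focal trait only
within the group-4 subtree at a rate targeting about eight changes
(resampling, boundedly, until at least six parsimony changes are realized),
which is the lability regime the published per-trait log-likelihoods
(around −30 for 55 taxa) imply.

What the generator does *not* emulate: real sequence content (fragments are
i.i.d. bases at a G/C target, with no phylogenetic signal), topological
conflict between the rival trees (they differ only in branch lengths, so
tests exercise the branch-length pathway in isolation), trait correlations,
and measurement error. Passing tests therefore demonstrate correctness of
the inference machinery and the direction and rough magnitude of the
branch-length effects — not that any particular empirical tree is right.

## Numerical choices

* Likelihoods are computed with per-edge rescaling of partials and summed
  in log space; posteriors are normalized per node and must sum to 1 within
  10⁻¹⁰.
* ER rate optimization is a deterministic 25-point coarse grid on log *q*
  followed by `optimize()` in the bracketing interval (tolerance 10⁻⁸);
  ARD uses L-BFGS-B from three fixed starts. No randomness enters any fit.
* GLS solves use Cholesky factorization of $C$; a singular $C$ (only
  possible with zero-length cherries, which the clamp prevents) is a hard
  error rather than a silent pseudo-inverse.
* Invariant characters return a boundary fit at the lower rate bound with
  `boundary = TRUE` instead of an exception, so trait tables with
  monomorphic columns run end to end.
* Ties and degenerate inputs: self-comparison of a tree with itself yields
  all ties and all variance ratios exactly 1; `sigma2 = 0` (constant tips)
  yields zero-variance reconstructions.

## Design decisions on genuinely open points

* **Mk flavour and root prior.** The source workflow does not record which
  Mk variant or root prior its reconstructions used. ER with a flat prior
  is the default of the implementation that workflow cites and the
  fewest-parameter choice; both are configuration options, and the
  arbitration arithmetic on the published per-trait table is independent of
  them (the table's values are inputs there).
* **"Non-consensual node".** Never formally defined at source; conflicting
  non-trivial bipartitions on the unrooted shared leaf set (RF/2 for binary
  trees) is the only reading under which "a single non-consensual node" is
  self-consistent, and it is outgroup-agnostic.
* **Continuous-trait scale.** No transform is applied by default; whether
  the original analyses log-transformed dimension-like traits is unknown,
  so the transform is explicit opt-in configuration rather than silent
  behaviour.
* **Column filtering.** The original supermatrix editing was manual.
  `filter_columns()` is a reproducible proxy (gap-fraction ≤ 0.2 by
  default, optional consensus threshold) and is documented as a proxy — it
  makes no claim to reproduce manually edited column counts.
* **Polytomies.** Accepted by the tree container and split machinery,
  rejected with a clear error by both ASR modules, which assume strictly
  binary rooted trees; resolving polytomies is the caller's decision, not
  something to do silently.
* **Command-line interface.** The exported functions are the primary
  interface; a thin `Rscript` wrapper (`inst/scripts/phyloarb.R`) provides
  shell subcommands for the common operations.

## Problem sizes used in the stochastic test suites

Oracle-equivalence suites run on 100 random trees of up to six leaves
(where exhaustive enumeration and the joint-normal conditional mean are
cheap and exact). Parameter-recovery suites use a 300-leaf Yule tree with
500 replicate Mk traits (true *q* = 0.5) and a 200-leaf tree with 200
replicate Brownian traits (true σ² = 1), recovering both means within 10%.
Robinson–Foulds agreement is checked on 500 random tree pairs. These sizes
give tight Monte-Carlo error while keeping the default test run fast.

## Known limitations

* Two states only; no multi-state or hidden-rate Mk models, no stochastic
  character mapping.
* Brownian motion only; no Ornstein–Uhlenbeck or early-burst models, and
  node variances condition on the plugged-in $\hat\sigma^2$.
* The raw-likelihood comparison between trees is deliberately informal — no
  AIC or Bayes-factor machinery — matching the workflow it reimplements.
* The re-rooting ASR recomputes a pruning pass per internal node
  (O(n) passes of O(n) each per trait); ample for tens of taxa, not tuned
  for thousands.
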