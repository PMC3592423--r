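---
title: "Inferring and analysing gene co-expression networks with splinenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and analysing gene co-expression networks with splinenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splinenet)
```

## The model

splinenet reconstructs an undirected gene network from a genes × samples
expression matrix by declaring an edge between two genes whenever their
statistical dependence, measured as mutual information (MI), is stronger
than expected under independence. MI captures non-linear as well as linear
co-expression and is symmetric, which is why the resulting network is
undirected; no directionality is inferred.

Three ideas make this workable at scale, and together they form the core of
the package:

1. **B-spline MI estimation.** Instead of a hard histogram, each
   observation distributes weight over up to *k* adjacent bins through
   B-spline basis functions of order *k* (`spline_basis()`), giving a
   smoothed density estimate and an `O(m)` MI computation per pair
   (`mutual_information()`). MI is `H(X) + H(Y) − H(X,Y)` with marginal
   and joint bin probabilities taken as means of those weights. Defaults
   are 10 bins and order 3, the convention established for this estimator
   family; both are arguments everywhere they matter.
2. **Rank transformation and a pooled permutation null.** Every profile is
   replaced by its ranks (`rank_transform()`), a monotone transformation
   under which MI is invariant in the population sense. After ranking,
   every profile is a permutation of `1..m`, so (a) every gene shares one
   marginal distribution — marginal entropy is computed once — and (b) a
   single sample of `MI(identity, random permutation)` values is a valid
   permutation null for *every* gene pair (`build_null()`). An observed MI
   is significant when it exceeds at least a fraction `1 − ε` of the `P`
   null values; we store the `⌈(1−ε)P⌉`-th order statistic as the
   threshold and keep edges strictly above it. This reproduces the
   at-least-a-fraction counting rule exactly, including at the resolution
   limit `ε = 1/P`, where an edge must beat all but one permutation. The
   resolvability guard `P·ε ≥ 1` is enforced. Defaults: `ε = 1e-4`,
   `P = 1e5`; both are recorded in the output's provenance.
3. **Data processing inequality (DPI) pruning.** If X → Y → Z form a
   Markov chain, `MI(X,Z)` can exceed neither `MI(X,Y)` nor `MI(Y,Z)`, so
   the weakest edge of a triangle is a candidate indirect interaction.
   `apply_dpi()` removes edge (i,k) whenever some common neighbour j gives
   `MI(i,k) ≤ (1−tol)·min(MI(i,j), MI(j,k))`. All decisions are evaluated
   against the input network (mark-and-sweep), so the result is
   independent of edge order. The inequality is deliberately non-strict:
   at `tol = 0` an exactly equal-weight triangle loses all three edges.
   This is loud but faithful to the inequality; pass a small positive
   tolerance to keep exact ties.

The all-pairs computation (`infer_network()`) is organised by
`block_schedule()`: the symmetric MI matrix is split into p × p blocks and
block pairs are assigned to p logical workers over `⌊p/2⌋ + 1` stages in a
circular-shift pattern; when p is even the final-stage blocks are assigned
twice with a half flag. In this package the schedule is a logical work
partition executed serially — the contract tested is that every unordered
block pair is covered exactly once and the result is identical for any
worker count. Distributed execution is out of scope.

## Preprocessing

Cross-experiment compendia need normalization before MI estimation:

* `qc_filter()` screens chips on a precomputed metrics table: scale factor
  within 3-fold of its experiment mean, BioB spike-in present, RLE centred
  at 0 and NUSE at 1 (each within 0.075) with IQR ≤ 0.75. Probe-level
  model fitting itself (producing those metrics) is platform-specific and
  not reimplemented; the package starts from the numeric table.
* `log_center()` takes log2 and subtracts each gene's per-experiment mean,
  so expression is comparable across experiments.
* `quantile_normalize()` equalises chip distributions (ties averaged).
  Whether to normalize jointly over all chips or per experiment is
  genuinely open; joint is the default (the whole compendium is rendered
  comparable), with `by_experiment = TRUE` as the switch.
* `iqr_filter()` removes genes whose profile IQR falls below 0.65 —
  profiles without dynamic range cannot support MI estimation. IQR uses
  linear interpolation between order statistics (R quantile type 7); the
  same rule is used by the tests' oracle.
* `cluster_probesets()` resolves redundant probe-set→gene maps: no-match
  probe-sets and those mapping to more than three genes are dropped, the
  rest are clustered by the transitive shares-a-gene relation, and each
  cluster keeps the member with the fewest targets (ties: smallest id, for
  determinism).

## Seed-driven subnetwork extraction

Given seed genes from a partially characterised pathway, the network is
converted to a Markov chain with MI-proportional transition probabilities
(`transition_matrix()`), and all genes are scored by the stationary
distribution of a walk that returns to the seeds with probability `r` per
step (`rank_genes()`, iterated to an L1 tolerance of 1e-10; typically a
few dozen iterations). The default `r = 0.3` balances seed fidelity
against exploration; `r = 1` degenerates to the preference vector. The
chain formally requires a connected aperiodic network; edge-less nodes are
handled by redirecting their mass to the preference vector (standard
stochastic completion, the default) or rejected with
`dangling = "error"`. Non-seed genes are then appended in rank order
(ties: lexicographic) until the induced subgraph first becomes one
connected component (`extract_subnetwork()`, incremental union-find); the
minimal rank-ordered connected subnetwork is returned. A higher-ranked
gene encountered before the connecting bridge legitimately stays in the
result — growth is by rank, not by shortest paths.

## Network statistics

`summarize_network()` reports density `2E/(n(n−1))`, average degree
`2E/n`, diameter and characteristic path length over *connected* pairs
(the giant component dominates; a disconnected or edge-less network
reports `NA` path metrics), average local clustering (degree < 2
contributes 0), and the random-graph expectations `L_rand = ln n / ln⟨k⟩`,
`C_rand = ⟨k⟩/n` used to diagnose small-world structure. Betweenness
(`node_betweenness()`) is unnormalized shortest-path centrality.
`powerlaw_fit()` fits a least-squares line to `(log k, log P(k))` and also
to the cumulative distribution; on empirical graphs the raw histogram's
tail is noisy and biases the density-fit slope low, so the cumulative
variant (`gamma_cum`, slope + 1) is the robust estimate and is the one
used in the package's own recovery checks. `modularity_test()` measures
functional modularity as the component count of the subgraph induced by a
gene set against a null of equal-sized random node sets (distributionally
identical to gene relabelling, cheaper); the add-one empirical p-value is
never 0 and, because the statistic is heavily tied, is conservative
(super-uniform) rather than exactly uniform under the null.

## The synthetic benchmark

`sample_topology()` draws scale-free directed acyclic truth networks by
preferential attachment (edges oriented old → new, so node order is a
topological order); `simulate_expression()` generates data where root
genes are standard normal and each regulated gene is
`f(Σ ±regulators) + noise` with `f` identity, logistic, or a 10× steep
logistic — three interaction families of increasing difficulty.
Activation/repression signs are drawn once per edge. This generator
emulates the *shape* of curated-network benchmark suites (heavy-tailed
topology, non-linear interaction kinetics) but makes no claim of
distributional equivalence to any specific simulator: it has no
transcription-kinetics ODEs, no biological noise model, and a single
sample condition. Passing recovery tests therefore demonstrates that the
estimator detects planted non-linear dependencies at realistic sizes
(100 genes × 200 samples, the scale used throughout), not that any
specific published benchmark score is reproduced.
`score_prediction()` computes precision/recall/F (direction ignored —
the method is undirected) and, from the weighted edge list, AUROC
(tie-corrected Mann-Whitney) and AUPR (threshold sweep) over all node
pairs with unpredicted pairs scored 0. `dream_score()` aggregates several
networks challenge-style: per-network empirical p-values of AUROC/AUPR
against random rankings, combined as −log10 geometric means; reproducing
a published challenge score additionally requires the external
gold-standard download, which is deliberately not bundled.

## Numerical choices and degenerate inputs

* Entropies in nats internally; `unit = "bits"` converts on output.
* `rank_transform()` breaks ties by original index (stable): ties are rare
  after normalization and determinism beats randomized tie-breaking.
* MI is clamped at 0 against floating-point cancellation.
* `MI(x,x) = H(x)` holds exactly for the order-1 (indicator) basis, where
  the joint collapses to the diagonal; for order ≥ 2 the fuzzy joint has
  off-diagonal mass and self-MI is merely the maximum over partners.
* Spline basis rows sum to 1 to ~1e-15 (partition of unity); the
  evaluation is a direct Cox–de Boor recursion, verified elementwise
  against an independent spline implementation in the tests.
* Empty networks, single-chip experiments, all-removed gene sets, cyclic
  truth networks and unreachable seeds all have defined behaviour (error
  or documented fallback) exercised by the tests.
* Problem sizes in the tests and acceptance script (20×200 calibration,
  100×200 recovery with `P = 1e4, ε = 1e-3`, 15-node DPI oracles, ≤50-node
  linear-solve oracles, 2000-node topology fits) were chosen as the
  smallest sizes at which each property is statistically decidable;
  they are the package's own test design.

## Known limitations

* No directionality: MI is symmetric; regulator→target orientation is
  outside what co-expression can deliver.
* The permutation null is shared across pairs by the rank-transform
  argument; pairs are not tested independently, and the edge-call rate on
  pure noise is calibrated to ε only in aggregate (binomial tolerance).
* DPI removes genuine triangles whose weakest edge is real (e.g.
  feed-forward loops); this is inherent to the inequality, not a bug.
* The CLI (`net_cli()`, `inst/cli/splinenet.R`) is a thin wrapper over the
  functions documented here; parallel/distributed execution, probe-level
  array processing and annotation enrichment are out of scope.
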