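# splinenet

Genome-scale gene co-expression network inference from expression
matrices, with seed-driven subnetwork extraction — for systems biologists
who have a genes × samples compendium (microarray or RNA-seq summaries)
and want a statistically thresholded interaction network plus tools to
mine it around pathways of interest.

## Method

An edge is drawn between genes *i* and *j* when their mutual information

> MI(i,j) = H(X_i) + H(X_j) − H(X_i, X_j)

is significant. Three components make this fast and rigorous:

* **B-spline MI estimator** — each observation spreads weight over up to
  *k* adjacent bins via B-spline basis functions (defaults: 10 bins,
  order 3), a smoothed alternative to hard histograms that computes MI in
  O(m) per pair.
* **Rank transform + pooled permutation null** — profiles are replaced by
  their ranks, making every profile a permutation of 1..m. MI is
  invariant under monotone transforms, all genes share one marginal
  entropy, and a single sample of P permutation MI values is a valid null
  for *every* pair: an edge is kept when its MI beats at least a fraction
  1 − ε of the permutations (defaults ε = 1e-4, P = 1e5).
* **DPI pruning** — by the data processing inequality, the weakest edge
  of a triangle is a candidate indirect interaction and is removed
  (tolerance-adjustable).

Around the core: microarray-style preprocessing (QC screening,
per-experiment log centering, quantile normalization, IQR filtering,
probe-set clustering), network statistics (density, path length,
clustering, betweenness, power-law degree fits, hubs, a functional
modularity permutation test), personalized random-walk gene ranking with
minimal connected subnetwork growth around seed genes, and a synthetic
benchmark generator with precision/recall/F and AUROC/AUPR scoring.

## Worked example

Using the bundled 20-gene fixture (two experiments, 30 chips, QC table):

```r
library(splinenet)
expr <- read_expression(system.file("extdata", "expr_small.tsv", package = "splinenet"))
qc   <- read_qc_metrics(system.file("extdata", "qc_small.tsv", package = "splinenet"))
norm <- preprocess(expr, qc = qc, iqr_threshold = 0.1)
#> QC: kept 28 / 30 chips
#> IQR filter: removed 0 / 20 genes
net <- infer_network(norm, bins = 5, epsilon = 0.02, n_perm = 2000, seed = 42)
net
#> Gene network: 20 nodes, 5 edges
#>   MI weights in [0.1344, 0.4862] nats
#>   params: bins=5, order=3, epsilon=0.02, n_perm=2000, seed=42, threshold=0.131982
summary(apply_dpi(net), hub_min_degree = 3)
#> Network summary
#>   nodes: 20   edges: 5
#>   density: 0.02632   average degree: 0.5
#>   diameter: 1   characteristic path length L: 1
#>   clustering C: 0   (random graph: L = NA, C = 0.025)
#>   hubs (degree >= 3): 0
```

Two chips fail QC (an out-of-band scale factor and a missing BioB call);
of 190 possible gene pairs, 5 beat the permutation threshold (0.132 nats)
at ε = 0.02 — the two planted co-expression pairs plus a few
borderline calls, as expected at that ε. Seed-driven extraction then
grows the minimal connected subnetwork around known genes:

```r
seeds <- read_seeds(system.file("extdata", "seeds_small.txt", package = "splinenet"))
extract_subnetwork(net, seeds, restart = 0.3)
#> Extracted subnetwork: 2 seed genes + 0 added genes, 1 edges
```

(The two seeds are directly linked, so nothing needs to be added.)

On synthetic benchmarks the full pipeline (simulate → infer → DPI →
score) recovers planted networks essentially perfectly at low noise:

```r
bench <- run_benchmark(n = 100, m = 200, type = "linear", reps = 3,
                       noise_sd = 0.1, epsilon = 1e-3, n_perm = 1e4, seed = 7)
#>   rep edges precision recall fscore f_random auroc aupr
#> 1   1    99         1      1      1     0.02     1    1
#> ...
```

A shell interface covering the whole pipeline (`preprocess`, `infer`,
`dpi`, `stats`, `modularity`, `extract`, `benchmark`) is installed at
`inst/cli/splinenet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/splinenet.R", package="splinenet"))')" \
  infer --expr norm.tsv --bins 10 --epsilon 1e-4 --perms 100000 --seed 42 --out net.tsv
```

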