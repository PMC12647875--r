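---
title: "Detecting topological turning points across the lifespan: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting topological turning points across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroepochs)
```

## The model

`neuroepochs` treats the lifespan development of structural network
topology as a trajectory through a low-dimensional space. The observable
is, per subject, a symmetric nonnegative connectivity matrix (streamline
counts between brain regions, 90 nodes in the reference configuration).
After thresholding and normalization, each subject is reduced to a vector
of organizational measures; measures are averaged within integer age bins
and z-scored, giving a matrix with one row per year of life. An ensemble of
3-D UMAP embeddings of that matrix represents the topological trajectory;
per embedding dimension, a degree-5 polynomial of age

$$\mathrm{Dim}(a) = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3
  + \beta_4 a^4 + \beta_5 a^5 + \varepsilon$$

is fit by least squares. A *turning point* is an age at which the fitted
gradient changes sign and the surrounding gradient mass is large enough:

$$T < \sum_{i-W}^{i+W} |G_i|,$$

with $G_i$ the analytic derivative at integer age $i$. Candidates within
$A$ years of each other (within or across dimensions) are interpreted as
one turning point and averaged. *Major* turning points are the peaks of a
Gaussian kernel density over the turning ages pooled across the ensemble,
and the intervals between them are the lifespan *epochs*.

The central assumptions are: (i) age-averaged, standardized metric
profiles carry enough signal that a 3-D embedding preserves the ordering
of developmental change; (ii) the trajectory is smooth enough at the
decade scale that a quintic captures its direction changes; and (iii)
direction changes that appear consistently across embedding parameters are
properties of the data, not of any single projection.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| nearest neighbors | 2–89 (88 values) | rows | local vs global structure per member |
| minimum distance | 0.1–1.0 (11 values) | – | packing of the embedding |
| components | 3 | – | embedding dimension |
| polynomial degree | 5 | – | flexibility of the trajectory fit |
| gradient window $W$ | 5 | years | span of the inflection filter |
| gradient threshold $T$ | 0.8 | gradient units | minimum local gradient mass |
| age window $A$ | 5 | years | merging distance for nearby candidates |
| KDE prominence | 5% of max | – | what counts as a major peak |
| fixed density target | 0.10 | fraction | density-controlled thresholding |
| modularity resolution $\gamma$ | 0.6 | – | scale of community detection |

The default grid therefore has $88 \times 11 = 968$ members. The gradient
threshold is expressed in the embedding's own units per year; because
features are z-scored before embedding, its scale is comparable across
datasets of similar size.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws stochastic-block-model count matrices whose
density falls with age (default 0.25 near birth to 0.12 in late life)
while Poisson edge counts grow with age, reproducing the qualitative
dense-weak-to-sparse-strong lifespan pattern; the within/between-block
contrast drifts upward with age so modularity moves too. Counts are
integer and right-skewed like streamline counts. The generator does *not*
attempt scanner or site effects (harmonization internals are out of scope
— only the mask/clip post-processing is implemented), spatial embedding of
regions, or realistic inter-subject topology correlations. Passing tests
on synthetic cohorts therefore demonstrates the *machinery* is correct and
calibrated, not that any particular neurobiological result would
replicate.

`generate_metric_trajectories()` plants piecewise-linear mean curves with
slope changes at known ages — by default every metric reverses direction
at every planted age with per-metric magnitudes drawn once in
[0.5, 1.5] — plus i.i.d. Gaussian noise. Real metric trajectories are
smoother and do not all turn at every turning point; the planted design is
deliberately the sharpest version of the hypothesis the detector is meant
to find.

## Numerical choices

- **Path lengths.** Edge length is the inverse weight, $1/w$ — the
  standard convention for weighted brain-network distance measures. Global
  efficiency counts unreachable pairs as zero; characteristic path length
  averages finite distances only and raises a `disconnected` flag, since
  both conventions exist in the literature and one has to be fixed.
- **Clustering.** The Onnela geometric-mean triangle intensity on
  max-normalized weights, the common weighted-undirected default. Nodes of
  degree < 2 score 0.
- **Small-worldness.** The literal clustering-to-path-length ratio has
  units, so values are normalized by the means of 10 (configurable)
  degree-preserving rewired nulls with the original weight multiset
  reassigned at random: $\sigma = (C/\langle C_0\rangle)/(L/\langle
  L_0\rangle)$, with $\sigma > 1$ read as small-world.
- **Modularity.** Louvain with 10 seeded restarts, each followed by a
  greedy single-node refinement pass, so the returned partition is locally
  optimal under single-node moves and the best $Q$ is kept
  deterministically. The resolution default 0.6 can be re-derived with
  `select_gamma()`, which picks the $\gamma$ maximizing the two-sample KS
  statistic between observed and rewired-null $Q$ distributions (ties go
  to the smallest $\gamma$).
- **Core/periphery.** The fit of a boolean core assignment is the cosine
  similarity between the weight vector and the ideal pattern (all pairs
  touching the core present, periphery empty), optimized by steepest-ascent
  label flips from strength-ranked and random restarts. On graphs small
  enough for exhaustive search the heuristic attains the global optimum in
  the package's tests.
- **k-core / s-core.** Reported as the node count of the last nonempty
  core under iterative peeling (the maximal shell); which level to report
  is genuinely underdetermined, so the peeling level is also returned.
- **Subgraph centrality** is computed on the binarized thresholded network
  by default (`binarize = FALSE` uses weights), via the eigen-decomposition
  $SC_i = \sum_j v_{ij}^2 e^{\lambda_j}$.
- **Thresholding ties.** Fixed-density mode keeps the top-$k$ edges with
  ties admitted in descending weight order, stable by node-pair index —
  deterministic and density-exact whenever weights permit. Variable mode
  brute-forces the single count cutoff over the sorted union of observed
  weights that brings the group mean density closest to target.
- **Polynomial conditioning.** Trajectories are fit in an age basis
  centered at the midpoint of the age range; a raw Vandermonde basis on
  ages 0–90 at degree 5 spans nine orders of magnitude and loses several
  digits. Candidates are refined from the integer-age sign flip to the
  derivative's real root (bisection tolerance $10^{-10}$) before rounding
  half-up to whole years.
- **KDE bandwidth.** Silverman's rule is the starting point but is capped
  at $A/2$ (2.5 years at defaults): Silverman targets unimodal densities
  and, on a small pooled set spanning the whole lifespan, inflates the
  bandwidth past the point where distinct turning points can be resolved
  at all. The pooled ages are also reflected at the age-range boundaries
  so the estimate is unbiased at 0 and 90 (and exactly flat for a uniform
  pool). Both the bandwidth and the prominence threshold are exposed.
- **Degenerate inputs.** Zero-variance feature columns are dropped with a
  warning; constant metrics within an epoch yield flagged `NA`
  correlations rather than silent omission; an all-zero matrix cannot be
  normalized; age bins with one subject pass through outlier removal
  untouched.

## Design choices that were genuinely open

- **Age smoother.** The density-target trend and peak/valley detection use
  a cross-validated cubic smoothing spline: the trend estimator only needs
  to be smooth and unbiased, and the spline keeps the package free of any
  additional modeling machinery.
- **Epoch boundaries.** Half-open intervals $[b_{k-1}, b_k)$ on rounded
  age, last epoch closed — a boundary age belongs to the *following*
  epoch. The alternative convention is one flag away in
  `assign_epochs()`.
- **LASSO standardization** happens within epoch (each epoch's model is
  fit on its own z-scored predictors); the one-SE rule is the default and
  the min-MSE fallback is taken, and flagged, only when one-SE zeroes
  every coefficient.
- **PCA scope.** Components are fit on subject-level standardized metrics
  across the whole lifespan, not on age-averages, so that score
  comparisons across epochs have subject-level degrees of freedom; DTW
  then uses per-age mean scores. Varimax uses Kaiser normalization.
- **Per-member seeds** are a deterministic hash of (nearest neighbors,
  minimum distance, global seed), so ensembles are reproducible member by
  member and invariant to evaluation order.

## Known limitations

- A degree-5 polynomial cannot place its derivative roots exactly at the
  bends of a piecewise-linear trajectory: on noiseless planted tents the
  detected candidates are displaced by one to three years even before any
  embedding is involved. Recovery is exact when the underlying trajectory
  is itself polynomial (the detect–filter–merge chain is exact in that
  case, as the test suite verifies); on tent-shaped ground truth the
  pipeline's accuracy is the ±2-year scale that the parameter-recovery
  tests assert, not zero.
- Very small ensembles (a handful of members) leave visible seed
  sensitivity in the KDE aggregation; the acceptance script uses a
  36-member grid for this reason, and the full 968-member default is
  preferable whenever runtime permits.
- The suite's stochastic calibration tests run at reduced sizes chosen for
  a laptop-scale test run (e.g. 50 parallel-analysis repeats at 200
  iterations each, 200 Welch null repeats, cohorts of 91–200 subjects);
  these sizes are stated in the tests themselves.
- Disconnected networks are handled by convention, not avoided: at 10%
  density a 90-node network is usually connected, but the flag should be
  checked before interpreting characteristic path length.
- `small_worldness` on very dense graphs is close to 1 by construction
  (rewired nulls of a complete graph are the graph itself); it is
  informative only away from the density extremes.
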