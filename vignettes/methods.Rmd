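---
title: "Methods: connectivity graphs, network measures, and their null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity graphs, network measures, and their null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restgraph)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, the assumptions and conventions the code
commits to, why the defaults are what they are, and what the synthetic
test substrate does and does not demonstrate about real data.

## From BOLD series to graphs

Resting-state functional connectivity treats the slow, spontaneous
fluctuations of the BOLD signal as the coupling of interest. The pipeline
assumes its input is already a regions × timepoints matrix per subject
and session — voxel preprocessing (motion correction, normalization,
nuisance regression) is out of scope, though `parcellate()` will reduce a
4-D volume over an integer atlas when the grids match exactly.

**Wavelet sub-band filtering.** Connectivity is estimated on a restricted
frequency band. `wavelet_subband_filter()` reconstructs each series from
the maximal-overlap discrete wavelet transform (MODWT) detail levels whose
dyadic support $[f_s/2^{j+1},\, f_s/2^j]$ overlaps the requested band
(default 0.06–0.1 Hz). At TR = 2.8 s ($f_s \approx 0.357$ Hz) that band
overlaps detail levels 1 (0.089–0.179 Hz) and 2 (0.045–0.089 Hz); no
single dyadic level matches 0.06–0.1 Hz exactly, so the filter sums every
overlapping level and records which ones it used. Design choices, all
configurable or documented because the convention is genuinely open:

* **Family**: Daubechies-4 (two vanishing moments). Short support keeps
  edge effects local at the ~200-sample lengths typical of a 10-minute
  run.
* **Boundary**: periodic (circular) extension — deterministic, exactly
  length-preserving, and it makes the transform exactly invertible, which
  the test suite exploits (details + smooth reconstruct the input to
  1e-12).
* **Alternative**: a hard zero-phase FFT band-pass behind the same
  interface (`method = "fft"`), for users who want literal band edges
  rather than dyadic ones.

The MODWT is shift-invariant and linear; both properties are asserted in
the tests (filter of a sum equals sum of filters; an in-band 0.08 Hz tone
retains ≥ 70 % of its variance, a 0.005 Hz tone ≤ 10 %, a constant maps
to zero).

**Correlation and thresholding.** `correlation_matrix()` computes the
Pearson correlation between all region pairs; the diagonal is defined as
0 and excluded everywhere (self-correlation carries no information, and
strength sums over neighbours only). `threshold_binarize()` keeps an edge
where $w_{ij} \ge r$ — the raw signed correlation, not $|w_{ij}|$, so
negative couplings never become edges; ties at the threshold are kept.
Strength is the one weighted measure and is always computed on the
complete weighted matrix, never a thresholded one. The default cost grid
is r = 0.3, 0.4, 0.5, 0.6, 0.7.

## Network measures

All measures operate on binary undirected graphs. Conventions for
degenerate cases, chosen once and applied uniformly:

* **Distances** are breadth-first edge counts; unreachable pairs are
  flagged (`Inf`), never coerced to a finite number.
* **Characteristic path length** averages finite distances only, per node
  and then over nodes with at least one reachable partner. An edgeless
  graph has no defined L and is flagged. This keeps L usable at high
  costs where graphs fragment.
* **Global efficiency** is the mean over ordered pairs of inverse
  distance with unreachable pairs contributing 0 — it degrades gracefully
  under fragmentation where L cannot.
* **Clustering** $C_i = R_i / \binom{D_i}{2}$ and **local efficiency**
  (global efficiency of the neighbour subgraph) are 0 for nodes with
  fewer than two neighbours: the denominators vanish, and 0 is the
  standard convention.
* **Betweenness** uses ordered source–target pairs with the
  $1/((N-1)(N-2))$ normalization, so a path-3 middle node scores exactly
  1. It is computed by Brandes' pair-dependency accumulation — exact, and
  tractable at the 116-node scale where naive path enumeration is not;
  the naive enumeration survives as the test oracle.
* **Hubs** are the top-k nodes by degree or betweenness with
  deterministic ties broken by label order.

Every measure is validated two ways: the worked schematic examples (a
node with three neighbours and two closed triangles has degree 3 and
clustering 2/3; a 5-chain endpoint has path length 4) and exhaustive
equality against independent brute-force oracles (Floyd–Warshall,
explicit triangle counting, exhaustive shortest-path enumeration) on 200
random graphs of up to 10 nodes, at 1e-12 or exact for integers.

## Community structure

`modularity_q()` evaluates Newman's
$Q = \frac{1}{2\alpha}\sum_{Z}\sum_{i,j \in Z}(A_{ij} - k_ik_j/2\alpha)$
for a given partition. `louvain_partition()` optimizes it greedily in the
usual two phases — local moves to the neighbouring module with the
largest gain, then aggregation of modules into super-nodes with self-loop
weights, repeated until no gain. Because Louvain is visit-order
sensitive and no canonical order exists, the node order is a seeded
shuffle per pass, ties in gain break toward the lowest module id, and the
best of `n_restarts = 10` seeded restarts is returned; the result is
fully deterministic given the seed. On graphs small enough for exhaustive
partition search (two triangles, two 4-cliques) the returned Q equals the
global optimum.

The participation coefficient $\Omega_j = 1 - \sum_c (\beta_{jc}/\beta_j)^2$
is 0 when all of a node's edges stay inside its own module and is bounded
by $1 - 1/M$ for M modules; isolated nodes are assigned 0 since the
formula is undefined at degree 0. Group-level community structure in
`run_pipeline()` is computed on the group-mean connectivity matrix per
session (per-subject partitions are available by calling the function
directly); the group-mean default avoids the module-matching problem
across subjects.

## Null models and small-worldness

Reference random graphs preserve the degree sequence exactly via repeated
double-edge swaps: edges (a,b), (c,d) become (a,d), (c,b) when no
self-loop or duplicate would arise. Defaults and bounds:

* `swaps_per_edge = 10` — a common mixing heuristic; no principled value
  exists, and the ring-lattice test confirms clustering is destroyed well
  before this budget.
* Failed draws are retried within a bounded budget (20 attempts per
  target swap) so termination is guaranteed; a graph with no legal swap
  (e.g. complete) is returned unchanged with a `saturated` flag.
* Each null sample's seed derives from the master seed by counter, so
  results are independent of evaluation order.

`small_worldness()` then reports $\gamma = C^{real}/C^{rand}$,
$\lambda = L^{real}/L^{rand}$, and $\sigma = \gamma/\lambda$, with the
null means and SDs over `n_null` graphs (default 1000; 100 is adequate
for the test-scale graphs, where the null SD of both parameters is a few
percent of their means). Null path lengths use the same finite-distance
convention as the real graph. Watts–Strogatz graphs (n = 100, k = 6,
p = 0.1) score σ well above 1 and Erdős–Rényi graphs score σ ≈ 1, the
expected separation.

## The synthetic data generator

`generate_dataset()` emulates the structure of a pre/post resting-state
study: by default 12 subjects, 116 regions, 214 timepoints at TR = 2.8 s
(a 10-minute run), fluctuations confined to 0.01–0.1 Hz, four equal-size
planted modules with within-module correlation 0.5 and between-module
0.1, and a post-session within-module increment `post_delta` (default
+0.1) emulating a learning-induced connectivity increase; a negative
increment models the reversed pattern of a pure-performance condition.

Mechanics, chosen for exact control of the target covariance: white
Gaussian noise is zero-phase band-pass filtered per region, standardized,
and mixed through the symmetric matrix square root of the planted
correlation matrix; white measurement noise (`noise_sd = 0.2`) is added
afterwards, and the signal correlation is pre-inflated by
$1 + \sigma_{noise}^2$ so that the correlation of the *observed* series
converges to the planted values exactly. If a requested matrix is not
positive semi-definite after the deltas it is projected to the nearest
PSD matrix (eigenvalue clipping) and the adjustment is recorded in the
ground truth. One master seed spawns per-subject substreams, so any
subject regenerates identically in isolation.

What the generator does **not** emulate: hemodynamic response shape,
scanner drift and physiological noise spectra, motion artefacts,
inter-subject anatomical variability, and the heavy-tailed, distance-
dependent structure of real connectivity matrices. Passing tests
demonstrate that the pipeline recovers *planted* effects of known form —
they bound implementation error, not the method's sensitivity on real
data.

## Statistics

Sessions are compared with the paired Wilcoxon signed-rank test: zero
differences dropped, ties mid-ranked, and the two-sided p-value computed
by exact enumeration of the $2^n$ sign patterns for n ≤ 25 (implemented
by convolution over doubled ranks, so tied ranks are handled exactly) and
by the continuity-corrected normal approximation beyond. Fewer than five
nonzero differences leaves the test flagged undefined rather than thrown,
so node-wise scans keep going. Under the null the p-values are calibrated:
the rejection rate at α = 0.05 over 200 replicate synthetic datasets with
`post_delta = 0` stays within the binomial 95 % band of α.

Corrections: Benjamini–Hochberg is the node-level default (116 tests per
measure and threshold); Bonferroni is available and is the appropriate
choice for the small family of between-group comparisons. Global claims
"across all costs" are operationalized as one test per threshold plus a
summary (`consistent_direction()`) requiring the same direction at every
threshold, since no pooling rule across costs is canonical.

## Threshold saturation: a known limitation

A planted within-module shift can be invisible to *degree* at thresholds
far from both correlation levels. With within-module correlation 0.5
(post 0.6) and between-module 0.1, the r = 0.3 threshold is saturated in
both sessions: essentially all within-module sample correlations lie
above it and essentially all between-module ones below, so the expected
post−pre degree change there is only ≈ +0.3 edges per node against a
subject-level SD near 1 — the reported direction at that single threshold
is close to a coin flip at n = 12, while strength (which integrates the
weight change directly) and the degree directions at r = 0.4–0.7 recover
the planted effect decisively, and the pooled 116-region strength test
reaches p < 0.001 by a wide margin. This is a property of threshold-based
degree analysis, not of the implementation; analyses that need
sensitivity at every cost should read strength, or choose thresholds
between the two correlation regimes.

## Problem sizes used by the test suite

The suites run at deliberately desk-scale sizes: oracle equivalence on
200 random graphs of ≤ 10 nodes; small-world behaviour on 100-node
graphs with 100 nulls; planted-effect recovery on the full 12 × 116 × 214
default configuration; null calibration on 200 replicates of a reduced
12 × 16 × 64 configuration (the calibration of the signed-rank test does
not depend on the region count, and the reduced size keeps the replicate
loop brisk). The full-scale analysis (1000 nulls per graph, five
thresholds, both sessions) is what `run_pipeline()` performs; its
per-stage cost is dominated by the null-model resampling.
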