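# restgraph

Graph-theoretic analysis of resting-state functional connectivity in R.

`restgraph` is for researchers who ask how a cognitive event — for example
a session of motor learning — reorganizes the brain's resting-state
networks between two scans. It takes regional BOLD time series (one matrix
of regions × timepoints per subject per session), isolates the
low-frequency fluctuations that define resting-state connectivity, builds
correlation graphs, and quantifies their topology with the standard
battery of network measures, null models, and paired nonparametric
statistics. A synthetic-data generator with planted connectivity structure
makes the whole pipeline testable without scanner data.

## The analysis in brief

1. **Sub-band filtering.** Each regional series is reconstructed from the
   maximal-overlap discrete wavelet transform (Daubechies-4) detail levels
   whose dyadic bands overlap a configured frequency interval (default
   0.06–0.1 Hz, the standard resting-state sub-band at TR = 2.8 s).
2. **Connectivity.** The Pearson correlation between every pair of
   regional series gives the weighted adjacency matrix `A_ij`; node
   *strength* is `S_i = Σ_j w_ij` on this complete weighted graph.
3. **Binary graphs.** `A` is thresholded at a range of costs
   (r = 0.3 … 0.7 by default; edge iff `w_ij ≥ r`) and binarized.
4. **Network measures.** Per node and per graph: degree `D_i`, shortest
   path length `L_i`, characteristic path length `L`, global efficiency
   (mean inverse shortest path), clustering coefficient
   `C_i = R_i / (D_i(D_i−1)/2)`, local efficiency (efficiency of each
   neighbour subgraph), betweenness centrality
   `X_i = 1/((N−1)(N−2)) Σ_{f≠j} Y_fj(i)/Y_fj` (Brandes algorithm), and
   hub identification.
5. **Null models and small-worldness.** Degree-preserving double-edge-swap
   rewiring yields reference random graphs; `γ = C_real/C_rand`,
   `λ = L_real/L_rand`, and the small-worldness coefficient `σ = γ/λ`
   (σ > 1 indicates small-world organization).
6. **Community structure.** Louvain modularity optimization gives a
   partition and its `Q`; the participation coefficient
   `Ω_j = 1 − Σ_c (β_jc/β_j)²` grades each node from fully intra-modular
   (0) to evenly distributed across modules (→ 1).
7. **Statistics.** Pre vs post sessions are compared with the paired
   Wilcoxon signed-rank test (exact with mid-ranked ties for n ≤ 25,
   continuity-corrected normal approximation beyond), with
   Benjamini–Hochberg or Bonferroni correction across nodes.

## Worked example

```r
library(restgraph)

cfg <- synthetic_config(n_subjects = 6, n_regions = 24, n_timepoints = 214,
                        module_sizes = c(12, 12), r_within = 0.55,
                        r_between = 0.25, post_delta = 0.15, seed = 7)
ds <- generate_dataset(cfg)            # 6 subjects x pre/post sessions
cm <- correlation_matrix(ds$subjects$sub01$pre)
g  <- threshold_binarize(cm, 0.4)
g
#> binary_graph: 24 nodes, 133 edges (threshold r = 0.4)
degrees(g)$mean                        #> 11.083
clustering_coefficients(g)$mean        #> 0.986
characteristic_path_length(g)$mean     #> 1.957
global_efficiency(g)                   #> 0.668

louvain_partition(g, seed = 7)
#> partition: 2 modules, Q = 0.4925    # exactly the two planted modules

small_worldness(g, n_null = 100, seed = 7)
#> small_world_result: gamma = 2.285, lambda = 1.289, sigma = 1.773 (n_null = 100)
```

The graph keeps the planted two-module structure (within-module
correlation 0.55 against 0.25 between), so clustering is high relative to
degree-matched rewired nulls (γ = 2.29) at a modest path-length cost
(λ = 1.29), giving σ = 1.77 — a small-world topology. Louvain recovers
the planted modules exactly with modularity Q = 0.49.

The full multi-subject flow — filter, correlate, threshold, measure,
community detection, null models, and the paired pre/post comparison with
a hashed run manifest — is driven by `run_pipeline(pipeline_config(...))`,
or from a shell via `inst/cli/restgraph.R` (subcommands `simulate`,
`connect`, `metrics`, `community`, `smallworld`, `compare`, `parcellate`,
`run-all`).

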