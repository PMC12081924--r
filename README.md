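# scrden

Single-cell trajectory inference from **gene rank differential expression
networks**.

Raw scRNA-seq expression values are noisy and dropout-ridden, but the
*ordering* of genes within a cell is far more stable. `scrden` builds its
cell features from that ordering: it converts expression to within-cell gene
ranks, restricts attention to the edges of a significance-filtered,
hard-thresholded Pearson co-expression network, and represents every cell by
the rank *differences* across those gene pairs. Cells are then clustered by
fusing similarity kernels built on three views of this gene-pair × cell
matrix, pseudotime is assigned per cluster from centroid geometry, and the
gene network is re-examined stage by stage to see how its topology changes
along a lineage. The package is aimed at analysts studying differentiation
or development who want a dropout-robust ordering of cell populations plus a
network-level readout of what changes between stages, and at methodologists
who want every step available as a plain, testable R function.

## Method overview

Starting from a genes × cells matrix `A0`:

1. **Preprocess** — drop mitochondrial/ribosomal/spike-in genes and genes
   expressed in ≤ 10% of cells; winsorize each gene to `[μ − 4σ, μ + 4σ]`;
   transform `A1 = log2(A0 + 1)`; keep feature genes whose intrinsic
   (excess-over-noise) fluctuation score is high and whose mean log
   expression exceeds a threshold `I`.
2. **Co-expression network** — Pearson correlation matrix `R` with t-test
   p-values; keep `|r|` for pairs with `p < 0.01` (matrix `B0`); choose a
   hard threshold `b0` by scale-free topology fit balanced against
   connectivity; edges are pairs with `b_ij > b0`.
3. **Rank network** — within each cell rank genes ascending (ordinal ties),
   giving `C0`; for each network edge `(g_k, g_l)` and cell `t` record
   `c_gt = rank(g_k, t) − rank(g_l, t)`; min–max normalize per cell to
   `[0, 1]`; optionally keep only the top-CV gene pairs.
4. **Ensemble clustering** — embed cells with PCA, t-SNE and UMAP; per view
   build a locally scaled Gaussian kernel
   `W_ij = exp(−ρ²_ij / (μ ε_ij))` with `ε_ij` the mean of the two cells'
   k-neighbour distances and their pair distance; normalize to a full
   kernel `P` (rows sum to 1, diagonal 1/2) and a sparse kNN kernel `S`
   (rows sum to 1/2); fuse by iterating
   `P⁽ᵛ⁾ ← S⁽ᵛ⁾ · mean_{k≠v}(P⁽ᵏ⁾) · S⁽ᵛ⁾ᵀ`; average into a fused affinity
   `E`; pick the cluster count from the eigengap of `L = D − E` and run
   spectral clustering.
5. **Trajectory** — pick the start cluster from marker genes; pseudotime
   `T ∈ [0, 1]` per cluster from its centroid's distance to the start
   centroid in the t-SNE plane; lineages are root-to-leaf paths of the
   centroid minimum spanning tree.
6. **Stage networks** — at each stage, edge weights are the stage-mean
   normalized rank differences, mirrored into a symmetric gene graph; edges
   below 0.2 are discarded for display; per-node **diversity**
   (scaled Shannon entropy of incident weights, `SE(i)/log k_i`) and
   **clustering coefficient** (`2 TR(i) / (k_i (k_i − 1))`) summarize the
   topology along each lineage.
7. **Evaluation** — pseudotemporal ordering score (POS, in `[−1, 1]`),
   robust score under per-gene Gaussian noise at 5/10/20% of each gene's
   SD, bubble sort index, Kendall correlation, ARI and NMI. A seeded
   branching negative-binomial simulator with dropout provides ground truth
   for all of them.

## Worked example

```r
library(scrden)

sim <- simulate_branching(n_genes = 400, n_cells = 300, n_branches = 2, seed = 1)
mods <- sim$truth$module_assignment
root_markers <- names(mods)[mods == "ramp_down"][1:10]   # high at t = 0

cfg <- scrden_config(n_clusters = 8, intrinsic_mean_min = 0.5,
                     entropy_quantile = 0.60, cv_min_edges = 20000)
res <- scrden_run(sim$matrix, cfg, start_markers = root_markers)
print(res)
#> scrden pipeline result
#>   genes: 400 screened -> 160 features; cells: 300
#>   co-expression: 4785 edges (b0 = 0.7); 4785 edge profiles kept
#>   clusters: 8 (user rule)
#>   start cluster: 1; 2 lineage path(s)
#>   cluster pseudotimes: 0 0.22 0.23 0.62 0.78 0.86 0.98 1
```

The simulated bifurcation is recovered as two lineage paths sharing a root
segment, and the inferred cell ordering closely matches the latent time the
cells were simulated at:

```r
evaluate_trajectory(res, sim$truth$cell_info)[c("pos", "bubble_sort_index", "kendall")]
#> POS 0.920  BSI 0.872  Kendall 0.744

key <- names(mods)[mods %in% c("branch1_up", "branch2_up")][1:12]
dynamics_along_path(res$profiles, res$model, key, res$model$paths[[1]])$summary
#>   cluster     T n_cells mean_diversity mean_cluster_coefficient
#> 1       1 0.000      56          1.000                    0.960
#> 2       4 0.233      33          0.999                    0.960
#> 3       7 0.616      28          0.986                    0.960
#> 4       6 0.855      32          0.985                    0.836
#> 5       5 0.982      33          0.985                    0.836
```

POS = 0.92 says the ordering is close to time-sorted once each cell pair is
weighted by its true time separation (POS = 1 is a perfect time-sorted
ordering, −1 its reverse); the bubble sort index says 87% of cell pairs are
in concordant order. The stage
table tracks the branch-marker subnetwork along the first lineage: its
clustering coefficient falls as the network loses cross-branch edges once
the lineages commit.

A command-line wrapper over the same functions is installed at
`inst/cli/scrden` (subcommands `simulate`, `run`, `preprocess`, `network`,
`cluster`, `trajectory`, `dynamics`, `evaluate`).

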