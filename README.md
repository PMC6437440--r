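# treetop

Branch-point detection in high-dimensional single-cell data via
ensembles of minimum spanning trees.

## What problem this solves, and for whom

Continuous biological processes — differentiation, maturation, immune
activation — appear in single-cell snapshots (mass/flow cytometry,
scRNA-seq) as trajectories through the space of marker abundances. A
*branch point* is a state where three or more trajectories meet: a
progenitor committing to one of several fates. Trajectory tools that
*assume* a tree will report branches whether or not the data contain
any. `treetop` is for analysts who need the prior question answered:
**is there statistical evidence of a branch point**, where is it, how
many branches join there (multifurcations included), and does branching
repeat at deeper levels of the hierarchy?

## The statistic

1. Spread `k` reference nodes through the (density-downsampled) data by
   k-means++ seeding; assign every cell to its nearest node (Voronoi
   tessellation, L1 distance by default).
2. Sample an ensemble of `n` spanning trees: each tree draws one cell
   uniformly per partition and joins them by a minimum spanning tree.
3. For each candidate node `x`, cut every tree at `x` and record in the
   consistency matrix `B_x` the fraction of trees in which each node
   pair lands in the same component. Single-linkage clustering of
   `1 − B_x` is cut at thresholds `p_cut = 0.01, …, 0.99`; with cluster
   sizes `N₁ ≥ N₂ ≥ N₃ ≥ …` (clusters of ≥ 2 nodes), the **raw
   branching score** of `x` is

       b(x) = (1/99) Σ_pcut Σ_{s≥3} N_s(p_cut)

   — the mean mass in the third-largest and smaller clusters, large
   exactly when cutting at `x` consistently produces ≥ 3 branches.
4. The maximum raw score `b_max` is divided by `b_ref`, the 95th
   percentile of maximum scores over synthetic *non-branching*
   (triangular, noise-free) datasets matched in cell count,
   dimensionality and `k`. The **relative branching score**
   `b_max / b_ref > 1` indicates evidence of branching; recursion into
   each branch while the score exceeds 1 reconstructs multi-level
   hierarchies.

A stochastic toggle-switch cascade simulator (Hill-kinetics production,
mass-action degradation, tau-leaping) generates hierarchically
branching ground-truth data for validation, alongside simple geometric
generators (path, circle, triangle, Gaussian blob, star).

## Worked example

Three-armed star data (10,000 cells, 5 dimensions) against a reference
built from 100 non-branching triangle datasets:

```r
library(treetop)

reft <- build_reference_table(data.frame(n_obs = 10000, d = 5, k = 50),
                              n_reps = 100,
                              config = treetop_config(k = 50, n_trees = 200),
                              seed = 1000)
cfg  <- treetop_config(k = 50, n_trees = 200, reference = reft, seed = 42)
star <- generate_geometry("star", n_obs = 10000, d = 5, arms = 3, seed = 42)
res  <- run_treetop(star, cfg)
res
#> <branching_result> branch point at node 9 | max raw score 12.27 | 3 branches
#>   relative branching score: 6.29 (evidence of branching)
normalized_mutual_information(res$cell_branches, star$labels)
#> [1] 0.9353544
```

The relative score of 6.29 says the star branches about six times more
strongly than the best non-branching topology of the same size; the
three recovered branches agree with the generating arms at NMI 0.94.
The same pipeline on a path gives 0, on a circle ≈ 0.5, on a filled
triangle ≈ 0.8 — no evidence of branching, as it should be. For
multi-level analyses use `recursive_treetop()`, which descends into
each branch while its relative score exceeds 1, and `hierarchy_depth()`
/ `write_results()` for the recovered hierarchy.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/treetop.R simulate --depth 2 --n-cells 20000 --seed 7 --out cells.csv
Rscript inst/cli/treetop.R run --input cells.csv --cofactor 5 --k 200 --reference ref_dir --outdir out
```

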