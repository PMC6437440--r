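---
title: "Detecting branch points in single-cell data with tree ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting branch points in single-cell data with tree ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(treetop)
```

## The problem

Differentiation, maturation and other continuous biological processes
trace trajectories through the state space of single cells — the space
of protein abundances (mass/flow cytometry) or transcript abundances
(scRNA-seq). A *branch point* is a location where three or more distinct
state trajectories meet: a progenitor state from which a cell commits to
one of several fates. Most trajectory-inference tools *assume* a tree
and will happily report branches in data that contain none. The question
this package answers is different: **is there evidence of a branch point
at all**, where is it, how many branches meet there, and does the
pattern repeat at deeper levels?

## The method

The pipeline has four stages.

**1. Reference nodes and Voronoi partitions.** After optional arcsinh
transformation (`cofactor = 5` for mass cytometry) and optional
diffusion-map reduction, density-based downsampling removes outliers
(below the 1st density percentile) and equalizes density (cells above
the 5th-percentile target density TD are retained with probability
TD/density — the SPADE rule). From the retained cells, `k = 200` (tests
and examples here use `k = 50`) reference nodes are spread evenly
through the data by k-means++ seeding; all retained cells join their
nearest node, giving a Voronoi tessellation. Density is the neighbour
count within a radius `sigma`; `suggest_sigma()` proposes five times
the median nearest-neighbour distance and reports distance quantiles so
users can judge the scale.

**2. An ensemble of trees.** Each of `n_trees` (default 1000; 200 in
the examples) trees picks one cell uniformly at random from every
partition and joins the `k` sampled cells by a minimum spanning tree
under the data metric (L1 by default). Edges are recorded against node
indices. Where the data have firm structure the same edges recur; in
diffuse regions the trees disagree. The superposition of all trees (the
*union graph*) can contain cycles no single tree can represent, which
is also what the force-directed layout draws.

**3. Branching scores.** For every candidate node `x`, every tree is
cut at `x`; the consistency matrix `B_x` records for each node pair the
proportion of trees in which both landed in the same component.
Single-linkage clustering of `1 - B_x` is cut at 99 thresholds
`p_cut = 0.01 ... 0.99`; at each threshold the cluster sizes
`N_1 >= N_2 >= N_3 >= ...` are computed and the **raw branching score**
is the mean over thresholds of `sum_{s>=3} N_s` — the mass in the
third-largest and smaller clusters. Two large clusters are what any
path-like process produces when cut; mass in a *third* cluster is the
signature of branching, and summing all clusters beyond the second
keeps multifurcations (4, 5, ... branches) visible even though each
individual branch is smaller.

**4. Relative scores.** Raw scores mean little in isolation — even
non-branching data produce nonzero scores. They are therefore divided
by `b_ref`, the 95th percentile of maximum raw scores over (by default
100, at full scale 1000) synthetic *non-branching* datasets matched in
cell count, dimensionality and `k`: uniform samples from a filled
triangle, the convex 2-D manifold that empirically produces the highest
non-branching scores. A **relative branching score** above 1 means the
data branch more than any such topology; `0.97` means no, or weak,
evidence. The precomputed grid covers `n_obs = 10,000 ... 100,000`,
`d = 5 ... 30`, `k = 50 ... 200` at noise `rho = 0` (240 cells);
`lookup_reference()` picks the nearest cell, breaking ties toward the
larger (more conservative) `b_ref`, warning and clamping for queries
outside the grid.

Recursion (`recursive_treetop()`) re-runs the whole pipeline inside
each identified branch — each branch is a fresh dataset with its own
density scale, nodes and reference lookup — descending while the
relative score exceeds 1 and at least `min_cells = 1000` cells remain.
Branch-point cells belong to no branch and are not passed down.

```{r example}
library(treetop)
reft <- build_reference_table(data.frame(n_obs = 10000, d = 5, k = 50),
                              n_reps = 100,
                              config = treetop_config(k = 50, n_trees = 200),
                              seed = 1000)
cfg <- treetop_config(k = 50, n_trees = 200, reference = reft, seed = 42)
star <- generate_geometry("star", n_obs = 10000, d = 5, arms = 3, seed = 42)
run_treetop(star, cfg)
```

## Design choices in detail

**Why 99 thresholds.** The score divides by 99 and sums
`p_cut = 0.01 ... 0.99`: the endpoints 0 and 1 are degenerate (one
cluster / all singletons) and carry no information.

**Cut semantics.** The dendrogram is cut at height `1 - p_cut` (plus
`1e-9` for floating-point safety, since similarities are exact
multiples of `1/n_trees`): nodes in different clusters then have
single-linkage co-branch probability strictly below `p_cut`.

**Branches need two nodes.** Singleton clusters are disregarded in the
size ranking. This matters more than it sounds: in data with
substantial noise in several dimensions, consistency matrices fragment
at high thresholds into dozens of singletons, and counting them as
"third and smaller clusters" inflates the scores of exactly the noisy,
non-branching data the reference is meant to reject — to the point of
inverting the expected ordering (noisy triangles scoring three times
higher than noise-free ones). Requiring two reference nodes per branch
restores the orderings this normalization depends on (noise-free
triangles above noisy triangles, paths and Gaussians) and roughly
doubles the separation between a 3-armed star and the triangle
reference. The reported branch *partition* still covers every node, so
no cell goes unlabelled.

**Ties.** Everywhere ties are broken deterministically: lowest node
index (argmax of scores, Voronoi assignment, Prim's MST), lowest
`p_cut`, larger `b_ref` in reference lookup. Exact ties are a real
concern with integer-valued simulated counts.

**Minimum input size.** Branch analysis on fewer than 1,000 cells asks
whether a handful of noisy high-dimensional points form branches; the
run refuses (`min_cells`), and lowering the floor requires an explicit
`allow_small` override.

**Triangle normalization.** The reference triangle is equilateral with
side 1, centred at the origin. The pipeline is invariant to rigid
motions and global scale (all distances pass through a data-adaptive
`sigma`), so shape is the only real choice; equilateral is the
symmetric one.

**Percentile convention.** `b_ref` uses linear interpolation between
order statistics (R's type 7), fixed for reproducibility.

## The synthetic-data generators

`generate_geometry()` supplies the validation manifolds — `path`
(1-D), `circle` (1-D with a cycle), `triangle` (2-D, the reference),
`blob` (an isotropic Gaussian: a 0-D manifold that is all measurement
spread), and `star` (the branching positive control, with ground-truth
arm labels).

`build_hierarchy_model()` + `tau_leap_simulate()` provide the
hierarchical positive control: a complete binary tree of stochastic
toggle switches. Each protein has Hill-kinetics production
`alpha * [gU^h+ / (gU^h+ + kappa+^h+)] * [kappa-^h- / (gS^h- + kappa-^h-)]`
(activation by the upstream protein `gU`, inhibition by its switch
partner `gS`; root proteins are constitutively activated) and
mass-action degradation `delta * g`. Simulation is fixed-step
tau-leaping: Poisson event counts per reaction per step, clamped at
zero, initial counts Poisson(100), 100 save points over `t = 0 ... 150`.
The step accuracy check compares propensities against their values at
the deterministic one-step prediction — intrinsic single-molecule noise
near sharp Hill thresholds is not step-size error and does not trigger
the warning.

The default rates (`alpha = 40`, `delta = 0.1`, `kappa_act = 200`,
`h_act = 4`, `kappa_inh = 5`, `h_inh = 4`) were chosen, once, by pilot
simulation against three requirements: each switch is bistable and
commits (winner at least five-fold above loser in over 95% of
trajectories) well before `t = 150`; both arms of every switch are
taken with substantial probability; and successive fate decisions are
*separated in time* — the activation gate sits at half the winner's
steady state, so a child switch engages only after its parent has
resolved. The last property is what real differentiation cascades have
and what makes a hierarchy visible in snapshot data at all: without it
the simulation collapses into a flat star of terminal fates.
Per-species parameter vectors and a `level_scale` knob allow other
regimes.

What the generators deliberately do not emulate: mRNA-level dynamics
and bursting, technical artefacts of cytometry (spillover, doublets,
bead normalization), library-size variation in scRNA-seq, and batch
effects. Passing the synthetic suite shows the statistic discriminates
the intended topologies under clean or Poisson-count noise — it does
not guarantee behaviour under heavy technical noise, where the
conservative noise-free reference makes false negatives (not false
positives) the expected failure mode.

## Problem sizes and costs

Distances, densities and the per-node consistency cubes are compiled
code; everything else is plain R on top of `stats::hclust`, `igraph`
and `data.table`. A full run at `n_obs = 10,000`, `d = 5`, `k = 50`,
200 trees takes about 1.5 s on one core, so the shipped examples and
tests build their 100-replicate reference tables in ~2 minutes. The
dense diffusion-map eigendecomposition is cubic in cell count and meant
for datasets up to a few thousand cells; larger data should arrive
already reduced. Memory for the consistency cube is `8 k^3` bytes
(64 MB at `k = 200`).

## Known limitations

* The relative score is calibrated against *noise-free* 2-D reference
  manifolds. Data whose structure is genuinely high-dimensional and
  diffuse score low; that is by construction conservative.
* Branch points closer together than the node spacing (`~ extent / k`)
  merge into a single multifurcation.
* The union graph and layout are for interpretation, not inference:
  only the relative score carries evidence.
* Disconnected cell populations violate the continuity assumption; the
  ensemble will bridge them arbitrarily and the score is not
  meaningful.
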