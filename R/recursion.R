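#' Configuration for a branch-analysis run
#'
#' Collects all tunable parameters of the pipeline. Defaults follow the
#' package-wide conventions: L1 distance, `k = 200` reference nodes,
#' 1000 trees, the 99-point dendrogram threshold grid, density
#' downsampling at the 1st (outlier) and 5th (target) density
#' percentiles, and a hard floor of 1,000 cells (branch analysis on
#' fewer cells amounts to asking whether a handful of noisy
#' high-dimensional points form branches, which is unanswerable, so the
#' run refuses).
#'
#' @param cofactor arcsinh cofactor applied to the input; `NULL` (the
#'   default) accepts the matrix as already transformed.
#' @param metric distance metric: `"L1"` (default), `"L2"` or `"angle"`.
#' @param sigma density radius; `NULL` selects one via [suggest_sigma()].
#' @param k number of reference nodes.
#' @param n_trees ensemble size.
#' @param thresholds dendrogram cut thresholds.
#' @param reference a `reference_table` for relative scoring, or `NULL`
#'   (raw scores only, `relative_score` stays `NA`).
#' @param seed default RNG seed for runs with this config.
#' @param min_cells minimum input size; values below 1,000 require
#'   `allow_small = TRUE`.
#' @param allow_small explicit override to lower `min_cells` below 1,000
#'   (for toy examples only).
#' @param recurse_threshold relative branching score above which
#'   [recursive_treetop()] descends into a branch (default exactly 1).
#' @param max_depth maximum recursion depth.
#' @param outlier_percentile,target_percentile density-downsampling
#'   percentiles, see [density_downsample()].
#' @param diffusion_components number of diffusion components to reduce
#'   to before analysis: 0 (default) skips diffusion maps, `"auto"`
#'   chooses by the eigenvalue elbow.
#' @return A `treetop_config` list.
#' @export
treetop_config <- function(cofactor = NULL, metric = "L1", sigma = NULL,
                           k = 200, n_trees = 1000,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           reference = NULL, seed = 1, min_cells = 1000,
                           allow_small = FALSE, recurse_threshold = 1,
                           max_depth = 3, outlier_percentile = 1,
                           target_percentile = 5, diffusion_components = 0) {
  if (min_cells < 1000 && !allow_small)
    stop("min_cells below 1,000 requires allow_small = TRUE")
  structure(list(cofactor = cofactor, metric = metric, sigma = sigma,
                 k = k, n_trees = n_trees, thresholds = thresholds,
                 reference = reference, seed = seed, min_cells = min_cells,
                 allow_small = allow_small,
                 recurse_threshold = recurse_threshold, max_depth = max_depth,
                 outlier_percentile = outlier_percentile,
                 target_percentile = target_percentile,
                 diffusion_components = diffusion_components),
            class = "treetop_config")
}

# preprocess -> nodes -> ensemble -> scoring, without reference lookup.
# Used both by run_treetop and by the reference-distribution builder
# (which cannot itself depend on a reference).
.treetop_raw <- function(x, config, seed) {
  x <- .as_cell_matrix(x)
  v <- x$values
  if (!is.null(config$cofactor)) v <- arcsinh_transform(v, config$cofactor)
  if (!identical(config$diffusion_components, 0)) {
    nc <- config$diffusion_components
    if (identical(nc, "auto")) {
      dm <- diffusion_map(v, n_components = min(20, nrow(v) - 1))
      nc <- elbow_components(dm$eigenvalues)
      v <- dm$embedding[, seq_len(nc), drop = FALSE]
    } else {
      v <- diffusion_map(v, n_components = nc)$embedding
    }
  }
  sigma <- config$sigma
  if (is.null(sigma))
    sigma <- suggest_sigma(v, metric = config$metric, seed = seed + 4L)
  dens <- compute_density(v, sigma = sigma, metric = config$metric)
  ds <- density_downsample(dens,
                           outlier_percentile = config$outlier_percentile,
                           target_percentile = config$target_percentile,
                           seed = seed + 1L)
  nodes <- .reference_node_set(v, ds, k = config$k, metric = config$metric,
                               seed = seed + 2L)
  ens <- build_ensemble(v, nodes, n_trees = config$n_trees,
                        metric = config$metric, seed = seed + 3L)
  res <- score_all_nodes(ens, thresholds = config$thresholds)
  res$downsample <- ds
  res$sigma <- as.numeric(sigma)
  res$analysis_dim <- ncol(v)
  res$cell_ids <- x$cell_ids
  res
}

#' Run the full branch-point analysis
#'
#' Executes the whole pipeline on one dataset: optional arcsinh
#' transform and diffusion-map reduction, density-based downsampling and
#' outlier removal, k-means++ reference-node selection, Voronoi
#' tessellation, tree-ensemble sampling, per-node branching scores, and
#' (when the config carries a reference table) the relative branching
#' score `b_max / b_ref`.
#'
#' @param x a [cell_matrix()] or numeric matrix with at least
#'   `config$min_cells` cells.
#' @param config a [treetop_config()].
#' @param seed RNG seed (defaults to `config$seed`); identical data,
#'   config and seed reproduce the identical result.
#' @return A `branching_result` (see [score_all_nodes()]) extended with
#'   `relative_score`, `b_ref`, `sigma`, `downsample`, `cell_ids` and
#'   the `config` used.
#' @export
run_treetop <- function(x, config = treetop_config(), seed = config$seed) {
  x <- .as_cell_matrix(x)
  n <- nrow(x$values)
  if (n < config$min_cells)
    stop("branch analysis requires at least ", config$min_cells,
         " cells (got ", n, "); results on so few cells would not be meaningful")
  res <- .treetop_raw(x, config, seed = seed)
  if (!is.null(config$reference)) {
    ref <- lookup_reference(config$reference, n_obs = n,
                            d = res$analysis_dim, k = config$k)
    res$b_ref <- ref$b_ref
    res$relative_score <- relative_score(max(res$raw_scores), ref)
  }
  res$config <- config
  res$seed <- seed
  res
}

#' Recursively detect a hierarchy of branch points
#'
#' Runs [run_treetop()] on the input and, whenever the relative branching
#' score exceeds `config$recurse_threshold` (default 1), descends
#' depth-first into the cell subset of every identified branch, each
#' branch re-analysed as a dataset in its own right (its own density
#' scale, nodes and reference lookup by its own size). Branch-point
#' cells belong to no branch and are not passed down. A branch becomes a
#' leaf when its parent's score shows no branching (`"score"`), it has
#' fewer than `min_cells` cells (`"min_cells"`), or `max_depth` is
#' reached (`"max_depth"`); the reason is recorded.
#'
#' @inheritParams run_treetop
#' @return A `branch_hierarchy`: list with the level's `result`, `depth`,
#'   `n_cells`, `cell_ids`, named `children` (one `branch_hierarchy` per
#'   recursed branch) and `leaf_reasons` (named character vector for the
#'   branches not recursed into).
#' @export
recursive_treetop <- function(x, config = treetop_config(), seed = config$seed) {
  x <- .as_cell_matrix(x)
  .recurse(x, config, seed, depth = 1L)
}

.recurse <- function(x, config, seed, depth) {
  res <- run_treetop(x, config, seed = seed)
  node <- list(result = res, depth = depth, n_cells = nrow(x$values),
               cell_ids = x$cell_ids, children = list(),
               leaf_reasons = character(0))
  class(node) <- "branch_hierarchy"
  branching <- !is.na(res$relative_score) &&
    res$relative_score > config$recurse_threshold
  if (!branching) {
    node$leaf_reasons <- setNames("score", "self")
    return(node)
  }
  labels <- as.character(seq_along(res$branches))
  for (b in seq_along(labels)) {
    cells <- which(res$cell_branches == labels[b])
    if (length(cells) < config$min_cells) {
      node$leaf_reasons[labels[b]] <- "min_cells"
    } else if (depth >= config$max_depth) {
      node$leaf_reasons[labels[b]] <- "max_depth"
    } else {
      node$children[[labels[b]]] <-
        .recurse(x[cells], config, seed = seed + 1000L * depth + b,
                 depth = depth + 1L)
    }
  }
  node
}

#' @export
print.branch_hierarchy <- function(x, ...) {
  show <- function(h, label, indent) {
    rs <- h$result$relative_score
    cat(strrep("  ", indent), label, ": ", h$n_cells, " cells",
        if (!is.na(rs)) paste0(", relative score ", format(rs, digits = 3)),
        "\n", sep = "")
    for (nm in names(h$children)) show(h$children[[nm]], paste("branch", nm), indent + 1)
    for (nm in names(h$leaf_reasons))
      cat(strrep("  ", indent + 1), if (nm == "self") "leaf" else
        paste("branch", nm, "leaf"), " (", h$leaf_reasons[[nm]], ")\n", sep = "")
  }
  show(x, "root", 0)
  invisible(x)
}

#' Depth of a recovered branch hierarchy
#'
#' Number of branching levels: 1 for a single branch point with no
#' recursion below it, 0 for a leaf-only (non-branching) run.
#'
#' @param hierarchy a `branch_hierarchy`.
#' @return Integer depth.
#' @export
hierarchy_depth <- function(hierarchy) {
  res <- hierarchy$result
  branching <- !is.na(res$relative_score) &&
    res$relative_score > hierarchy$result$config$recurse_threshold
  if (!branching) return(0L)
  if (length(hierarchy$children) == 0) return(1L)
  1L + max(vapply(hierarchy$children, hierarchy_depth, integer(1)))
}
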