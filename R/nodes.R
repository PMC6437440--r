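#' Select reference nodes by k-means++ seeding
#'
#' Picks `k` cells spread evenly through the data: the first uniformly at
#' random from the kept cells, each subsequent one with probability
#' proportional to the squared distance to its nearest already-chosen
#' node (the canonical k-means++ seeding rule; the squared weighting is
#' retained even when the data metric is L1). No Lloyd iterations follow:
#' the seeded positions are used directly as nodes.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param kept indices of cells eligible as nodes (non-outlier,
#'   non-downsampled); defaults to all cells.
#' @param k number of reference nodes (at least 2, at most `length(kept)`).
#' @param metric distance metric.
#' @param seed RNG seed.
#' @return Integer vector of `k` distinct cell (row) indices.
#' @export
select_reference_nodes <- function(x, kept = NULL, k, metric = "L1", seed = NULL) {
  v <- .values(x)
  if (is.null(kept)) kept <- seq_len(nrow(v))
  if (k < 2) stop("k must be at least 2")
  if (k > length(kept))
    stop("k = ", k, " exceeds the ", length(kept),
         " available cells; consider a smaller k for datasets with fewer cells")
  vk <- v[kept, , drop = FALSE]
  .with_seed(seed, {
    chosen <- integer(k)
    chosen[1] <- sample.int(length(kept), 1)
    mind <- .cross_dist(vk, vk[chosen[1], , drop = FALSE], metric)[, 1]
    w <- mind^2
    for (i in seq_len(k - 1) + 1) {
      if (sum(w) <= 0)
        stop("fewer than k distinct cells available; consider a smaller k")
      chosen[i] <- sample.int(length(kept), 1, prob = w)
      d_new <- .cross_dist(vk, vk[chosen[i], , drop = FALSE], metric)[, 1]
      mind <- pmin(mind, d_new)
      w <- mind^2
    }
    kept[chosen]
  })
}

#' Assign cells to their closest reference node
#'
#' Voronoi tessellation of the retained cells around the reference nodes;
#' ties go to the lowest node index.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param node_cells row indices of the reference-node cells.
#' @param metric distance metric.
#' @param retained indices of cells to assign (kept plus downsampled;
#'   outliers get no assignment); defaults to all cells.
#' @return Integer vector over all cells: the 1-based node index for
#'   every retained cell, `NA` elsewhere.
#' @export
assign_voronoi <- function(x, node_cells, metric = "L1", retained = NULL) {
  v <- .values(x)
  if (is.null(retained)) retained <- seq_len(nrow(v))
  a <- rep(NA_integer_, nrow(v))
  a[retained] <- nearest_node_cpp(v[retained, , drop = FALSE],
                                  v[node_cells, , drop = FALSE],
                                  .metric_code(metric))
  a
}

# bundle node selection + tessellation (internal pipeline step)
.reference_node_set <- function(x, ds, k, metric, seed) {
  node_cells <- select_reference_nodes(x, kept = ds$kept, k = k,
                                       metric = metric, seed = seed)
  retained <- sort(c(ds$kept, ds$downsampled))
  assignment <- assign_voronoi(x, node_cells, metric = metric, retained = retained)
  # each node is its own nearest node (distance 0), so all partitions are nonempty
  sizes <- tabulate(assignment[retained], nbins = k)
  members <- split(retained, factor(assignment[retained], levels = seq_len(k)))
  structure(list(node_cells = node_cells, k = k, assignment = assignment,
                 retained = retained, partition_sizes = sizes,
                 members = members, metric = metric),
            class = "reference_node_set")
}

#' @export
print.reference_node_set <- function(x, ...) {
  cat("<reference_node_set> k =", x$k, "nodes over",
      length(x$retained), "retained cells\n")
  invisible(x)
}
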