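#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm with a deterministic lowest-index tie-break, so exact
#' ties (common with integer-valued synthetic counts) always resolve to
#' the same tree.
#'
#' @param dist_matrix square symmetric nonnegative matrix with zero
#'   diagonal; non-finite entries are an error.
#' @return A `data.frame` with columns `i`, `j` (1-based vertex indices,
#'   `i < j`) and `weight`, ordered by `(i, j)`.
#' @export
minimum_spanning_tree <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) != ncol(dist_matrix)) stop("distance matrix must be square")
  if (any(!is.finite(dist_matrix))) stop("distance matrix contains non-finite entries")
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-12) stop("distance matrix must be symmetric")
  e <- prim_mst_cpp(dist_matrix)
  out <- data.frame(i = e[, 1], j = e[, 2],
                    weight = dist_matrix[cbind(e[, 1], e[, 2])])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Sample one spanning tree from the Voronoi partitions
#'
#' Draws one cell uniformly at random from every Voronoi partition and
#' joins the `k` sampled cells by a minimum spanning tree; edges are
#' recorded against the node indices, weighted by the data-space distance
#' between the two sampled cells.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param nodes a `reference_node_set` (see [assign_voronoi()] and
#'   [select_reference_nodes()]; built internally by [run_treetop()]).
#' @param metric distance metric.
#' @param seed RNG seed.
#' @return A `tree_sample`: list with `edges` (data.frame `i`, `j`,
#'   `weight` over node indices) and `sampled_cells` (k row indices).
#' @export
sample_tree <- function(x, nodes, metric = "L1", seed = NULL) {
  v <- .values(x)
  k <- nodes$k
  members <- nodes$members
  if (is.null(members))
    members <- split(nodes$retained,
                     factor(nodes$assignment[nodes$retained], levels = seq_len(k)))
  if (any(lengths(members) == 0)) stop("internal error: empty Voronoi partition")
  sampled <- .with_seed(seed, {
    vapply(members, function(m) {
      if (length(m) == 1) m else m[sample.int(length(m), 1)]
    }, integer(1), USE.NAMES = FALSE)
  })
  D <- .cross_dist(v[sampled, , drop = FALSE], metric = metric)
  structure(list(edges = minimum_spanning_tree(D), sampled_cells = sampled),
            class = "tree_sample")
}

#' Build an ensemble of sampled spanning trees
#'
#' Samples `n_trees` trees independently (per-tree seeds derived as
#' `seed + tree_index`, giving reproducible streams); all trees share the
#' node index space `1..k`.
#'
#' @inheritParams sample_tree
#' @param n_trees number of trees (default 1000; the consistency-matrix
#'   entries are proportions over trees, so 1000 trees give roughly
#'   +/-0.03 sampling error at 95% confidence).
#' @return A `tree_ensemble`: list with matrices `edge_i`, `edge_j`,
#'   `edge_w` (`n_trees` x `k-1`), `sampled_cells` (`n_trees` x `k`),
#'   plus `n_trees`, `k`, `nodes`, `metric`.
#' @export
build_ensemble <- function(x, nodes, n_trees = 1000, metric = "L1", seed = NULL) {
  if (n_trees < 1) stop("n_trees must be at least 1")
  k <- nodes$k
  edge_i <- edge_j <- matrix(0L, n_trees, k - 1)
  edge_w <- matrix(0, n_trees, k - 1)
  sampled <- matrix(0L, n_trees, k)
  for (t in seq_len(n_trees)) {
    tr <- sample_tree(x, nodes, metric = metric,
                      seed = if (is.null(seed)) NULL else seed + t)
    edge_i[t, ] <- tr$edges$i
    edge_j[t, ] <- tr$edges$j
    edge_w[t, ] <- tr$edges$weight
    sampled[t, ] <- tr$sampled_cells
  }
  structure(list(edge_i = edge_i, edge_j = edge_j, edge_w = edge_w,
                 sampled_cells = sampled, n_trees = n_trees, k = k,
                 nodes = nodes, metric = metric),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("<tree_ensemble>", x$n_trees, "trees over", x$k, "reference nodes\n")
  invisible(x)
}

# edges of tree t as a data.frame (internal)
.tree_edges <- function(ensemble, t) {
  data.frame(i = ensemble$edge_i[t, ], j = ensemble$edge_j[t, ],
             weight = ensemble$edge_w[t, ])
}

#' Union graph of a tree ensemble
#'
#' Superposition of all trees: an edge is present wherever it occurred in
#' at least one tree, annotated with the proportion of trees containing
#' it and the mean distance over those trees. Unlike any individual tree,
#' the union graph can contain cycles (e.g. for data sampled around a
#' circle, each tree breaks the circle at a different point).
#'
#' @param ensemble a `tree_ensemble`.
#' @return A `union_graph`: data.frame with columns `i`, `j`, `frequency`
#'   (in `(0, 1]`), `mean_distance`; attributes `k` and `n_trees`.
#' @export
union_graph <- function(ensemble) {
  dt <- data.table::data.table(i = as.vector(ensemble$edge_i),
                               j = as.vector(ensemble$edge_j),
                               w = as.vector(ensemble$edge_w))
  agg <- dt[, list(frequency = .N / ensemble$n_trees, mean_distance = mean(w)),
            by = c("i", "j")]
  data.table::setorder(agg, i, j)
  out <- as.data.frame(agg)
  attr(out, "k") <- ensemble$k
  attr(out, "n_trees") <- ensemble$n_trees
  class(out) <- c("union_graph", "data.frame")
  out
}

#' Prune a union graph to its strongest connected backbone
#'
#' Removes low-frequency edges for display clarity: applies the largest
#' frequency threshold, among the observed edge frequencies, that still
#' leaves the graph connected (so bridges are always retained, however
#' rare).
#'
#' @param graph a `union_graph` (must be connected).
#' @return The pruned `union_graph`, connected by construction, with the
#'   threshold used stored in attribute `"threshold"`.
#' @export
prune_union_graph <- function(graph) {
  k <- attr(graph, "k")
  g_full <- igraph::graph_from_data_frame(graph[, c("i", "j")], directed = FALSE,
                                          vertices = data.frame(name = seq_len(k)))
  if (!igraph::is_connected(g_full)) stop("union graph must be connected")
  for (f in sort(unique(graph$frequency), decreasing = TRUE)) {
    sub <- graph[graph$frequency >= f, , drop = FALSE]
    g <- igraph::graph_from_data_frame(sub[, c("i", "j")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(k)))
    if (igraph::is_connected(g)) {
      attrs <- attributes(graph)
      out <- sub
      attr(out, "k") <- attrs$k
      attr(out, "n_trees") <- attrs$n_trees
      attr(out, "threshold") <- f
      class(out) <- c("union_graph", "data.frame")
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("internal error: no connected threshold found")
}
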