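# Independent oracles and fixture builders used across tests.

# Decode a Pruefer sequence into a labelled tree (edge matrix, 1-based).
# Standard textbook construction; independent of the package's MST code.
prufer_decode <- function(seq, k) {
  degree <- rep(1L, k)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, k - 1, 2)
  ptr <- 0L
  for (e in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[e, ] <- sort(c(leaf, seq[e]))
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[e]] <- degree[seq[e]] - 1L
  }
  last <- which(degree == 1L)
  edges[k - 1, ] <- sort(last)
  edges
}

random_tree <- function(k) {
  if (k == 2) return(matrix(c(1L, 2L), 1, 2))
  prufer_decode(sample.int(k, k - 2, replace = TRUE), k)
}

# Brute-force MST: enumerate all k^(k-2) labelled spanning trees via
# Pruefer sequences and return the minimum total weight.
brute_force_mst_weight <- function(D) {
  k <- nrow(D)
  if (k == 2) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    edges <- prufer_decode(as.integer(seqs[r, ]), k)
    w <- sum(D[edges])
    if (w < best) best <- w
  }
  best
}

# Closed-form branching score of a single tree cut at node x: total size
# of all components beyond the two largest, among components holding at
# least 2 nodes (a branch needs two reference nodes). Computed via
# igraph, independent of the package's consistency/cut machinery.
cut_score_oracle <- function(edges, x, k) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  g <- igraph::delete_vertices(g, x)
  sizes <- sort(igraph::components(g)$csize, decreasing = TRUE)
  sizes <- sizes[sizes >= 2]
  if (length(sizes) < 3) 0 else sum(sizes[-(1:2)])
}

# Wrap identical copies of one tree as a tree_ensemble (deterministic
# ensemble; every partition is the node itself).
identical_tree_ensemble <- function(edges, n_trees, k,
                                    weights = rep(1, nrow(edges))) {
  nodes <- structure(list(node_cells = seq_len(k), k = k,
                          assignment = seq_len(k), retained = seq_len(k),
                          partition_sizes = rep(1L, k),
                          members = as.list(seq_len(k)), metric = "L1"),
                     class = "reference_node_set")
  structure(list(edge_i = matrix(rep(edges[, 1], each = n_trees), n_trees),
                 edge_j = matrix(rep(edges[, 2], each = n_trees), n_trees),
                 edge_w = matrix(rep(weights, each = n_trees), n_trees),
                 sampled_cells = matrix(rep(seq_len(k), each = n_trees), n_trees),
                 n_trees = n_trees, k = k, nodes = nodes, metric = "L1"),
            class = "tree_ensemble")
}

# ensemble from an explicit list of edge data.frames (i, j, weight)
ensemble_from_trees <- function(trees, k) {
  n_trees <- length(trees)
  edge_i <- t(vapply(trees, function(e) as.integer(e$i), integer(k - 1)))
  edge_j <- t(vapply(trees, function(e) as.integer(e$j), integer(k - 1)))
  edge_w <- t(vapply(trees, function(e) {
    if (is.null(e$weight)) rep(1, k - 1) else as.numeric(e$weight)
  }, numeric(k - 1)))
  nodes <- structure(list(node_cells = seq_len(k), k = k,
                          assignment = seq_len(k), retained = seq_len(k),
                          partition_sizes = rep(1L, k),
                          members = as.list(seq_len(k)), metric = "L1"),
                     class = "reference_node_set")
  structure(list(edge_i = edge_i, edge_j = edge_j, edge_w = edge_w,
                 sampled_cells = matrix(rep(seq_len(k), each = n_trees), n_trees),
                 n_trees = n_trees, k = k, nodes = nodes, metric = "L1"),
            class = "tree_ensemble")
}

# block-structured consistency matrix with given block sizes and
# off-block similarity
block_consistency <- function(sizes, off = 0) {
  m <- sum(sizes)
  B <- matrix(off, m, m)
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    B[idx, idx] <- 1
  }
  dimnames(B) <- list(seq_len(m), seq_len(m))
  B
}

two_blob_data <- function(n_per, sep = 20, d = 2, sd = 0.5) {
  v <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
             matrix(rnorm(n_per * d, 0, sd), n_per, d))
  v[(n_per + 1):(2 * n_per), 1] <- v[(n_per + 1):(2 * n_per), 1] + sep
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
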