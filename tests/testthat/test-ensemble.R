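test_that("minimum spanning tree matches enumeration on small instances", {
  # 3 nodes with distances 01:1, 02:2, 12:3 -> edges {01, 02}
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  mst <- minimum_spanning_tree(D)
  expect_equal(mst[, c("i", "j")], data.frame(i = c(1, 1), j = c(2, 3)),
               ignore_attr = TRUE)
  expect_equal(sum(mst$weight), 3)
  # collinear points form a path
  line <- matrix(c(0, 1, 2), ncol = 1)
  Dl <- as.matrix(dist(line, method = "manhattan"))
  mstl <- minimum_spanning_tree(Dl)
  expect_equal(sum(mstl$weight), 2)
  expect_equal(nrow(mstl), 2)
  expect_error(minimum_spanning_tree(matrix(c(0, Inf, Inf, 0), 2)), "finite")
  # brute-force equivalence over random instances
  set.seed(13)
  for (r in 1:20) {
    k <- sample(3:6, 1)
    v <- matrix(runif(k * 2), k)
    D <- as.matrix(dist(v))
    expect_equal(sum(minimum_spanning_tree(D)$weight),
                 brute_force_mst_weight(D), tolerance = 1e-12)
  }
})

test_that("sampled trees are spanning trees with uniform within-partition draws", {
  set.seed(14)
  v <- matrix(rnorm(200 * 2), 200)
  ds <- density_downsample(compute_density(v, 0.5), seed = 1)
  nodes <- treetop:::.reference_node_set(v, ds, k = 10, metric = "L1", seed = 2)
  tr <- sample_tree(v, nodes, seed = 3)
  # tree oracle: k-1 edges, connected, acyclic
  g <- igraph::graph_from_data_frame(tr$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = 1:10))
  expect_equal(nrow(tr$edges), 9)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::components(g)$no, 1)
  # edge weights equal data distances between the sampled cells
  e1 <- tr$edges[1, ]
  expect_equal(e1$weight,
               pairwise_distance(v[tr$sampled_cells[e1$i], ],
                                 v[tr$sampled_cells[e1$j], ], "L1"))
  # determinism
  expect_identical(sample_tree(v, nodes, seed = 3), tr)
  # singleton partitions make sampling deterministic
  vs <- matrix(seq(0, 90, by = 10), ncol = 1)
  nodes_s <- treetop:::.reference_node_set(
    vs, density_downsample(rep(1, 10)), k = 10, metric = "L1", seed = 1)
  tr_s <- sample_tree(vs, nodes_s, seed = 99)
  expect_equal(sort(tr_s$sampled_cells), 1:10)
})

test_that("within a partition of two, each cell is drawn about half the time", {
  v <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  nodes <- structure(list(node_cells = c(1L, 3L), k = 2L,
                          assignment = c(1L, 1L, 2L, 2L), retained = 1:4,
                          partition_sizes = c(2L, 2L),
                          members = list(c(1L, 2L), c(3L, 4L)), metric = "L1"),
                     class = "reference_node_set")
  draws <- vapply(1:10000, function(s) sample_tree(v, nodes, seed = s)$sampled_cells[1],
                  integer(1))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.02)
})

test_that("ensembles share the node space and respect seeds", {
  set.seed(15)
  v <- matrix(rnorm(300 * 2), 300)
  ds <- density_downsample(compute_density(v, 0.5), seed = 1)
  nodes <- treetop:::.reference_node_set(v, ds, k = 8, metric = "L1", seed = 2)
  e1 <- build_ensemble(v, nodes, n_trees = 1, seed = 5)
  expect_equal(e1$n_trees, 1)
  e2 <- build_ensemble(v, nodes, n_trees = 20, seed = 5)
  e3 <- build_ensemble(v, nodes, n_trees = 20, seed = 6)
  expect_identical(e2$nodes, e3$nodes)
  expect_false(identical(e2$edge_i, e3$edge_i) && identical(e2$edge_j, e3$edge_j))
  expect_identical(build_ensemble(v, nodes, n_trees = 20, seed = 5), e2)
  # every tree in an ensemble is a spanning tree
  for (t in 1:20) {
    g <- igraph::graph_from_data_frame(treetop:::.tree_edges(e2, t)[, 1:2],
                                       directed = FALSE,
                                       vertices = data.frame(name = 1:8))
    expect_true(igraph::is_connected(g))
  }
})

test_that("union graph records frequencies and mean distances", {
  # identical trees: union equals the tree, all frequencies 1
  tr <- data.frame(i = c(1, 2), j = c(2, 3), weight = c(1, 2))
  ens <- ensemble_from_trees(list(tr, tr, tr), k = 3)
  u <- union_graph(ens)
  expect_equal(u$frequency, c(1, 1))
  expect_equal(u$mean_distance, c(1, 2))
  # two trees sharing one edge
  tr2 <- data.frame(i = c(1, 1), j = c(2, 3), weight = c(1, 4))
  u2 <- union_graph(ensemble_from_trees(list(tr, tr2), k = 3))
  freq <- setNames(u2$frequency, paste(u2$i, u2$j))
  expect_equal(unname(freq["1 2"]), 1)
  expect_equal(unname(freq["2 3"]), 0.5)
  expect_equal(unname(freq["1 3"]), 0.5)
  # frequencies sum to (k-1): total edge slots over trees / n_trees
  expect_equal(sum(u2$frequency), 2)
})

test_that("union graph of circular data contains a cycle though each tree is acyclic", {
  set.seed(16)
  x <- generate_geometry("circle", n_obs = 1500, d = 2, seed = 17)
  v <- x$values
  ds <- density_downsample(compute_density(v, 0.3), seed = 1)
  nodes <- treetop:::.reference_node_set(v, ds, k = 12, metric = "L1", seed = 2)
  ens <- build_ensemble(v, nodes, n_trees = 50, seed = 3)
  u <- union_graph(ens)
  expect_gt(nrow(u), nodes$k - 1)  # more edges than any single tree
  g <- igraph::graph_from_data_frame(u[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = 1:12))
  expect_gt(igraph::ecount(g) - igraph::vcount(g) +
              igraph::components(g)$no, 0)  # cyclomatic number > 0
})

test_that("pruning keeps the largest threshold that preserves connectivity", {
  # all frequencies equal: unchanged
  tr <- data.frame(i = c(1, 2, 3), j = c(2, 3, 4), weight = 1)
  u <- union_graph(ensemble_from_trees(list(tr), k = 4))
  p <- prune_union_graph(u)
  expect_equal(nrow(p), 3)
  # a minimum-frequency bridge must be retained
  edges <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 3, 4),
                      frequency = c(1, 1, 0.9, 0.1), mean_distance = 1)
  attr(edges, "k") <- 4; attr(edges, "n_trees") <- 10
  class(edges) <- c("union_graph", "data.frame")
  pb <- prune_union_graph(edges)
  expect_true(any(pb$i == 3 & pb$j == 4))
  expect_equal(attr(pb, "threshold"), 0.1)
  # output is connected on random ensembles
  set.seed(18)
  v <- matrix(rnorm(400 * 2), 400)
  ds <- density_downsample(compute_density(v, 0.5), seed = 1)
  nodes <- treetop:::.reference_node_set(v, ds, k = 10, metric = "L1", seed = 2)
  for (s in 1:3) {
    u2 <- union_graph(build_ensemble(v, nodes, n_trees = 30, seed = s))
    p2 <- prune_union_graph(u2)
    g <- igraph::graph_from_data_frame(p2[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = 1:10))
    expect_true(igraph::is_connected(g))
  }
})
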