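test_that("cutting a tree at a node yields one component per incident edge", {
  path <- data.frame(i = c(1, 2), j = c(2, 3))
  lab <- cut_tree_at_node(path, 2, k = 3)
  expect_equal(length(unique(lab)), 2)
  lab_leaf <- cut_tree_at_node(path, 1, k = 3)
  expect_equal(length(unique(lab_leaf)), 1)
  star <- data.frame(i = rep(1, 4), j = 2:5)
  expect_equal(length(unique(cut_tree_at_node(star, 1, k = 5))), 4)
  # component count equals the degree of the removed node on random trees
  set.seed(23)
  for (r in 1:20) {
    k <- sample(4:12, 1)
    edges <- random_tree(k)
    x <- sample.int(k, 1)
    deg <- sum(edges == x)
    expect_equal(length(unique(cut_tree_at_node(
      data.frame(i = edges[, 1], j = edges[, 2]), x, k = k))), deg)
  }
})

test_that("consistency matrix equals hand-enumerated co-branch proportions", {
  # tree 1: path a-x-b-c, tree 2: path b-x-a-c with a = 1, x = 2, b = 3, c = 4
  t1 <- data.frame(i = c(1, 2, 3), j = c(2, 3, 4), weight = 1)
  t2 <- data.frame(i = c(2, 1, 1), j = c(3, 2, 4), weight = 1)
  ens <- ensemble_from_trees(list(t1, t2), k = 4)
  B <- consistency_matrix(ens, 2)
  expect_equal(B["1", "3"], 0)    # a and b never share a branch
  expect_equal(B["1", "4"], 0.5)  # a and c share one in two trees
  expect_equal(diag(unclass(B)), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(B)))
  # entries are multiples of 1/n_trees
  expect_true(all(abs(B * 2 - round(B * 2)) < 1e-12))
  # matches the compiled consistency cube
  cube <- treetop:::consistency_cube_cpp(ens$edge_i, ens$edge_j, 4)
  expect_equal(unclass(B), cube[, , 2][-2, -2], ignore_attr = TRUE)
})

test_that("raw branching score matches block structure closed forms", {
  # two blocks: never a third cluster, score 0 at every threshold
  out2 <- raw_branching_score(block_consistency(c(12, 8)))
  expect_equal(out2$score, 0)
  # three blocks 10, 6, 4: score 4 (third block at every threshold)
  out3 <- raw_branching_score(block_consistency(c(10, 6, 4)))
  expect_equal(out3$score, 4)
  expect_equal(sort(lengths(out3$branches), decreasing = TRUE), c(10, 6, 4))
  # five blocks 8, 6, 4, 3, 2: score 4 + 3 + 2 = 9
  out5 <- raw_branching_score(block_consistency(c(8, 6, 4, 3, 2)))
  expect_equal(out5$score, 9)
  # fewer than 3 nodes: score 0, single branch
  tiny <- block_consistency(c(1, 1))
  expect_equal(raw_branching_score(tiny)$score, 0)
  expect_error(raw_branching_score(block_consistency(c(3, 3)), thresholds = c(0, 0.5)),
               "inside")
})

test_that("raising off-block similarity never increases the score", {
  scores <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95),
                   function(off) raw_branching_score(
                     block_consistency(c(10, 6, 4), off = off))$score,
                   numeric(1))
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("deterministic ensembles score as the closed-form cut sizes at every node", {
  set.seed(24)
  for (r in 1:20) {
    k <- sample(5:12, 1)
    edges <- random_tree(k)
    ens <- identical_tree_ensemble(edges, n_trees = 6, k = k)
    res <- score_all_nodes(ens)
    oracle <- vapply(seq_len(k), function(x) cut_score_oracle(edges, x, k),
                     numeric(1))
    expect_equal(res$raw_scores, oracle, tolerance = 1e-9)
    # bound: score cannot exceed (k-1) minus the two largest components
    expect_true(all(res$raw_scores <= k - 3 + 1e-9))
  }
})

test_that("score_all_nodes finds the centre of a star and maps branches to cells", {
  # star with arms of 10, 6 and 4 nodes joined at node 1
  arm_sizes <- c(10, 6, 4)
  k <- sum(arm_sizes) + 1
  edges <- NULL
  nid <- 2
  for (a in seq_along(arm_sizes)) {
    prev <- 1
    for (s in seq_len(arm_sizes[a])) {
      edges <- rbind(edges, c(prev, nid))
      prev <- nid
      nid <- nid + 1
    }
  }
  edges <- t(apply(edges, 1, sort))
  ens <- identical_tree_ensemble(edges, n_trees = 4, k = k)
  res <- score_all_nodes(ens)
  expect_equal(res$branch_node, 1)
  expect_equal(res$raw_scores[1], 4)
  expect_true(all(res$raw_scores[-1] < 4))
  expect_equal(sort(lengths(res$branches), decreasing = TRUE), c(10, 6, 4))
  # cells of the branch node partition are labelled as the branch point
  expect_equal(res$cell_branches[1], "branch point")
  expect_equal(sum(res$cell_branches == "branch point", na.rm = TRUE), 1)
  # branch labels cover exactly the non-branch-node cells
  expect_equal(sum(res$cell_branches %in% as.character(1:3)), k - 1)
  # identical path trees: all raw scores 0
  path_edges <- cbind(1:4, 2:5)
  res_path <- score_all_nodes(identical_tree_ensemble(path_edges, 3, 5))
  expect_equal(res_path$raw_scores, rep(0, 5))
  # argmax ties break to the lowest node index
  expect_equal(res_path$branch_node, 1)
})

test_that("mean tree distance averages path weights from the branch point", {
  t1 <- data.frame(i = c(1, 2), j = c(2, 3), weight = c(1, 1))
  ens1 <- ensemble_from_trees(list(t1), k = 3)
  expect_equal(mean_tree_distance(ens1, 1), c(0, 1, 2))
  # two trees with path weights 2 and 4 between nodes 1 and 3
  ta <- data.frame(i = c(1, 2), j = c(2, 3), weight = c(1, 1))
  tb <- data.frame(i = c(1, 2), j = c(2, 3), weight = c(2, 2))
  ens2 <- ensemble_from_trees(list(ta, tb), k = 3)
  expect_equal(mean_tree_distance(ens2, 1)[3], 3)
})

test_that("marker ANOVA ranks separated species first with Bonferroni cap", {
  set.seed(25)
  n <- 100
  strong <- c(rnorm(n, 0), rnorm(n, 5))       # 5 sigma separation
  null1 <- rnorm(2 * n); null2 <- rnorm(2 * n)
  v <- cbind(strong = strong, null1 = null1, null2 = null2)
  branches <- rep(c("1", "2"), each = n)
  out <- marker_anova(v, branches)
  expect_equal(out$species[1], "strong")
  expect_lt(out$p_bonferroni[1], 1e-6)
  expect_true(all(out$p_bonferroni <= 1))
  # agreement with an independently coded F statistic
  grp <- factor(branches)
  ybar <- mean(strong)
  ssb <- sum(tapply(strong, grp, function(z) length(z) * (mean(z) - ybar)^2))
  ssw <- sum(tapply(strong, grp, function(z) sum((z - mean(z))^2)))
  f_manual <- (ssb / 1) / (ssw / (2 * n - 2))
  expect_equal(out$F[out$species == "strong"], f_manual, tolerance = 1e-8)
  # identical groups: p near 1
  flat <- cbind(a = rep(c(1, 2), 50))
  out_flat <- marker_anova(cbind(a = rep(c(1, 2), 100)),
                           rep(c("1", "2"), each = 100))
  expect_gt(out_flat$p_value[1], 0.9)
  # branch-point cells are excluded; tiny branches dropped with warning
  b2 <- branches
  b2[1] <- "branch point"
  expect_silent(marker_anova(v, b2))
  b3 <- c(branches, "3")
  expect_warning(marker_anova(rbind(v, 0), b3), "fewer than 2")
})

test_that("normalized mutual information matches hand-computed cases", {
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(normalized_mutual_information(c("a", "a", "b", "b"),
                                             c("x", "x", "y", "y")), 1)
  expect_equal(normalized_mutual_information(c(1, 2, 1, 2), c(1, 1, 1, 1)), 0)
  # independent partitions: joint entropy factorizes, NMI 0
  expect_equal(normalized_mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # excluded labels are dropped before computing
  expect_equal(normalized_mutual_information(c("1", "1", "2", "2", "ungated"),
                                             c("a", "a", "b", "b", "a")), 1)
  expect_equal(normalized_mutual_information(c(1, NA), c(1, 1)), 0)
  expect_error(normalized_mutual_information(1:3, 1:2), "equal length")
})
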