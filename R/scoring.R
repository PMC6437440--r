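#' Cut a tree at a node
#'
#' Removes node `x` and its incident edges from a spanning tree; the
#' remaining nodes fall into connected components ("branches"), one per
#' edge incident to `x`.
#'
#' @param tree a `tree_sample` or an edge data.frame with columns
#'   `i`, `j` over nodes `1..k`.
#' @param x node index to cut at.
#' @param k total number of nodes (inferred from the edges if missing).
#' @return Named integer vector of branch labels (1-based, arbitrary but
#'   consistent ids) over the nodes other than `x`.
#' @export
cut_tree_at_node <- function(tree, x, k = NULL) {
  edges <- if (inherits(tree, "tree_sample")) tree$edges else tree
  if (is.null(k)) k <- max(edges$i, edges$j)
  adj <- vector("list", k)
  for (e in seq_len(nrow(edges))) {
    a <- edges$i[e]; b <- edges$j[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, k)
  comp[x] <- 0L
  nc <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.na(comp[v]) && v != x) {
          comp[v] <- nc
          queue <- c(queue, v)
        }
      }
    }
  }
  setNames(comp[-x], seq_len(k)[-x])
}

#' Consistency matrix of a node
#'
#' For candidate branch point `x`, entry `(i, j)` is the proportion of
#' trees in which nodes `i` and `j` fell into the same branch when the
#' tree was cut at `x`. Entries are multiples of `1/n_trees`; the
#' diagonal is 1. A true branch point yields a block structure: nodes
#' within a branch co-occur in almost all trees, nodes across branches in
#' almost none.
#'
#' This reference implementation loops over trees in R via
#' [cut_tree_at_node()]; the pipeline ([score_all_nodes()]) computes all
#' k matrices at once in compiled code.
#'
#' @param ensemble a `tree_ensemble`.
#' @param x candidate node index.
#' @return A `consistency_matrix`: symmetric `(k-1) x (k-1)` matrix over
#'   the other nodes, dimnames = node indices, attribute `node_x`.
#' @export
consistency_matrix <- function(ensemble, x) {
  k <- ensemble$k
  others <- seq_len(k)[-x]
  B <- matrix(0, k - 1, k - 1, dimnames = list(others, others))
  for (t in seq_len(ensemble$n_trees)) {
    lab <- cut_tree_at_node(.tree_edges(ensemble, t), x, k = k)
    B <- B + outer(lab, lab, "==")
  }
  B <- B / ensemble$n_trees
  attr(B, "node_x") <- x
  class(B) <- c("consistency_matrix", class(B))
  B
}

#' Raw branching score of a consistency matrix
#'
#' Single-linkage hierarchical clustering on the dissimilarity `1 - B`;
#' for every threshold `p_cut` the dendrogram is cut at height
#' `1 - p_cut` (so nodes in different clusters have co-branch probability
#' below `p_cut`), giving cluster sizes `N_1 >= N_2 >= N_3 >= ...`. The
#' raw score is the mean over thresholds of `sum_{s>=3} N_s`: the total
#' mass in the third-largest and smaller clusters. Summing all clusters
#' beyond the second (rather than `N_3` alone) keeps multifurcations
#' detectable, where the third branch is necessarily smaller. Units are
#' reference-node counts.
#'
#' A branch must contain at least two reference nodes: singleton
#' clusters are disregarded in the size ranking `N_1 >= N_2 >= ...`.
#' Diffuse consistency matrices (e.g. from high-dimensional noise)
#' otherwise shatter into singletons at high thresholds, and counting
#' those as branch mass inflates the scores of exactly the non-branching
#' noisy data the score is meant to reject. The reported branch
#' partition still covers all nodes, singletons included.
#'
#' The reported `best_pcut` is the threshold maximizing `N_3` (ties:
#' larger `sum_{s>=3} N_s`, then lower `p_cut`), and `branches` are the
#' clusters at that threshold.
#'
#' @param B a [consistency_matrix()] (or any symmetric similarity matrix
#'   with entries in `[0, 1]`).
#' @param thresholds cut thresholds strictly inside `(0, 1)`; default the
#'   99-point grid `0.01, 0.02, ..., 0.99`.
#' @return List with `score`, `best_pcut`, and `branches` (list of
#'   integer node-id vectors, ordered by decreasing size).
#' @export
raw_branching_score <- function(B, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  B <- unclass(B)
  m <- nrow(B)
  ids <- if (!is.null(rownames(B))) as.integer(rownames(B)) else seq_len(m)
  if (m < 3)
    return(list(score = 0, best_pcut = thresholds[1],
                branches = list(ids)))
  hc <- hclust(as.dist(1 - B), method = "single")
  # cut heights: + eps so that pairs with similarity exactly p_cut merge
  ct <- cutree(hc, h = (1 - thresholds) + 1e-9)
  n3 <- s3 <- numeric(length(thresholds))
  for (col in seq_along(thresholds)) {
    sizes <- sort(tabulate(ct[, col]), decreasing = TRUE)
    sizes <- sizes[sizes >= 2]   # singletons are not branches
    if (length(sizes) >= 3) {
      n3[col] <- sizes[3]
      s3[col] <- sum(sizes[-(1:2)])
    }
  }
  best <- order(-n3, -s3, thresholds)[1]
  memb <- ct[, best]
  sizes <- sort(table(memb), decreasing = TRUE)
  branches <- lapply(names(sizes), function(cl) ids[memb == as.integer(cl)])
  list(score = mean(s3), best_pcut = thresholds[best], branches = branches)
}

#' Score every node of an ensemble for branching
#'
#' Computes the consistency matrix and raw branching score for every
#' candidate node, reports the argmax node (ties: lowest index) as the
#' branch point, and maps its branches onto cells through the Voronoi
#' assignment. Cells of the branch-node partition are labelled
#' `"branch point"`, belonging to no branch; outliers stay `NA`.
#'
#' @param ensemble a `tree_ensemble`.
#' @param thresholds dendrogram cut thresholds, see
#'   [raw_branching_score()].
#' @return A `branching_result`: list with `raw_scores` (per node),
#'   `branch_node`, `best_pcut`, `branches` (list of node-index vectors,
#'   decreasing size), `node_branch` (per node: branch id, 0 for the
#'   branch node), `cell_branches` (per cell: `"1"`, `"2"`, ...,
#'   `"branch point"` or `NA`), `relative_score` (`NA` until a reference
#'   distribution is applied), plus the `ensemble`.
#' @export
score_all_nodes <- function(ensemble, thresholds = seq(0.01, 0.99, by = 0.01)) {
  k <- ensemble$k
  cube <- consistency_cube_cpp(ensemble$edge_i, ensemble$edge_j, k)
  raw_scores <- numeric(k)
  per_node <- vector("list", k)
  for (x in seq_len(k)) {
    B <- cube[, , x][-x, -x, drop = FALSE]
    others <- seq_len(k)[-x]
    dimnames(B) <- list(others, others)
    per_node[[x]] <- raw_branching_score(B, thresholds)
    raw_scores[x] <- per_node[[x]]$score
  }
  branch_node <- which.max(raw_scores)   # first maximum: lowest index on ties
  best <- per_node[[branch_node]]
  node_branch <- integer(k)              # 0 = branch node
  for (b in seq_along(best$branches)) node_branch[best$branches[[b]]] <- b
  nodes <- ensemble$nodes
  cell_branches <- rep(NA_character_, length(nodes$assignment))
  ret <- nodes$retained
  lbl <- as.character(node_branch[nodes$assignment[ret]])
  lbl[nodes$assignment[ret] == branch_node] <- "branch point"
  cell_branches[ret] <- lbl
  structure(list(raw_scores = raw_scores, branch_node = branch_node,
                 best_pcut = best$best_pcut, branches = best$branches,
                 node_branch = node_branch, cell_branches = cell_branches,
                 relative_score = NA_real_, b_ref = NA_real_,
                 ensemble = ensemble),
            class = "branching_result")
}

#' @export
print.branching_result <- function(x, ...) {
  cat("<branching_result> branch point at node", x$branch_node,
      "| max raw score", format(max(x$raw_scores), digits = 4),
      "|", length(x$branches), "branches\n")
  if (!is.na(x$relative_score))
    cat("  relative branching score:", format(x$relative_score, digits = 3),
        if (x$relative_score > 1) "(evidence of branching)" else
          "(no or weak evidence of branching)", "\n")
  invisible(x)
}

#' Mean tree distance from the branch point
#'
#' For every node, the mean over trees of the weighted path length from
#' the branch node to that node along each tree; serves as a pseudotime
#' axis for plotting marker profiles along branches.
#'
#' @param ensemble a `tree_ensemble`.
#' @param branch_node node index of the identified branch point.
#' @return Numeric vector of length k (0 at the branch node).
#' @export
mean_tree_distance <- function(ensemble, branch_node) {
  k <- ensemble$k
  total <- numeric(k)
  for (t in seq_len(ensemble$n_trees)) {
    adj <- vector("list", k)
    ei <- ensemble$edge_i[t, ]; ej <- ensemble$edge_j[t, ]; ew <- ensemble$edge_w[t, ]
    for (e in seq_len(k - 1)) {
      adj[[ei[e]]] <- rbind(adj[[ei[e]]], c(ej[e], ew[e]))
      adj[[ej[e]]] <- rbind(adj[[ej[e]]], c(ei[e], ew[e]))
    }
    dist_t <- rep(NA_real_, k)
    dist_t[branch_node] <- 0
    queue <- branch_node
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (is.na(dist_t[v])) {
          dist_t[v] <- dist_t[u] + nb[r, 2]
          queue <- c(queue, v)
        }
      }
    }
    total <- total + dist_t
  }
  total / ensemble$n_trees
}

#' Rank species by differential abundance across branches
#'
#' One-way ANOVA F-test per species across the branch groups, Bonferroni
#' corrected (p multiplied by the number of species, capped at 1) and
#' ranked by ascending corrected p. Branch-point and unassigned cells are
#' excluded; branches with fewer than 2 cells are dropped with a warning.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param cell_branches per-cell branch labels, as in
#'   [score_all_nodes()]'s `cell_branches`.
#' @return data.frame with columns `species`, `F`, `p_value`,
#'   `p_bonferroni`, sorted by ascending corrected p.
#' @export
marker_anova <- function(x, cell_branches) {
  v <- .values(x)
  keep <- !is.na(cell_branches) & cell_branches != "branch point"
  g <- factor(cell_branches[keep])
  small <- names(which(table(g) < 2))
  if (length(small)) {
    warning("excluding branches with fewer than 2 cells: ",
            paste(small, collapse = ", "))
    keep2 <- !(as.character(g) %in% small)
    g <- droplevels(g[keep2])
    v <- v[keep, , drop = FALSE][keep2, , drop = FALSE]
  } else {
    v <- v[keep, , drop = FALSE]
  }
  if (nlevels(g) < 2) stop("need at least 2 branches with at least 2 cells each")
  d <- ncol(v)
  res <- lapply(seq_len(d), function(s) {
    a <- anova(lm(v[, s] ~ g))
    c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
  })
  res <- do.call(rbind, res)
  out <- data.frame(species = colnames(v), F = res[, 1], p_value = res[, 2],
                    p_bonferroni = pmin(res[, 2] * d, 1))
  out[order(out$p_bonferroni, out$p_value), , drop = FALSE]
}

#' Normalized mutual information between two labelings
#'
#' `2 I(A; B) / (H(A) + H(B))`: 1 for identical partitions up to
#' relabelling, 0 for independent ones, and defined as 0 when both
#' entropies vanish. Cells whose label is missing or listed in `exclude`
#' (e.g. ungated populations) are removed first.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param exclude labels to drop before computing (besides `NA`).
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(labels_a, labels_b,
                                          exclude = c("ungated", "")) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  keep <- !is.na(labels_a) & !is.na(labels_b) &
    !(labels_a %in% exclude) & !(labels_b %in% exclude)
  a <- factor(labels_a[keep])
  b <- factor(labels_b[keep])
  n <- length(a)
  if (n == 0) stop("no cells left after exclusions")
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha + hb == 0) return(0)
  mi <- 0
  nz <- which(joint > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    pij <- joint[nz[r, 1], nz[r, 2]]
    mi <- mi + pij * log(pij / (pa[nz[r, 1]] * pb[nz[r, 2]]))
  }
  as.numeric(2 * mi / (ha + hb))
}
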