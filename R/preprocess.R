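#' Inverse hyperbolic sine transform
#'
#' Standard variance-stabilizing transform for cytometry abundances:
#' `asinh(x / cofactor)`. Cofactor 5 is conventional for mass cytometry
#' and around 150 (tag-dependent) for fluorescence flow cytometry.
#'
#' @param values numeric vector or matrix of raw abundances.
#' @param cofactor positive scale divisor applied before `asinh`.
#' @return Transformed values with the shape of the input.
#' @export
arcsinh_transform <- function(values, cofactor = 5) {
  .assert_positive(cofactor, "cofactor")
  asinh(values / cofactor)
}

#' Distance between two abundance vectors
#'
#' Supported metrics are L1 (Manhattan, the package default throughout),
#' L2 (Euclidean) and angle distance (arc-cosine of cosine similarity,
#' in `[0, pi]`, undefined for zero vectors).
#'
#' @param a,b numeric vectors of equal length.
#' @param metric one of `"L1"`, `"L2"`, `"angle"`.
#' @return A single nonnegative distance.
#' @export
pairwise_distance <- function(a, b, metric = "L1") {
  if (length(a) != length(b)) stop("vectors must have equal length")
  cross_dist_cpp(matrix(as.numeric(a), nrow = 1),
                 matrix(as.numeric(b), nrow = 1), .metric_code(metric))[1, 1]
}

# full or rectangular distance matrix between row sets (internal)
.cross_dist <- function(X, Y = X, metric = "L1") {
  cross_dist_cpp(X, Y, .metric_code(metric))
}

#' Neighbour-count density of every cell
#'
#' The local density of cell `i` is the number of cells within distance
#' `sigma` of it, including itself (so density is always at least 1).
#' This is the density definition used by density-dependent downsampling
#' of cytometry data (SPADE-style).
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param sigma positive radius in data-space units.
#' @param metric distance metric, see [pairwise_distance()].
#' @return A `density_profile`: list with integer `density` per cell and
#'   the `sigma` used.
#' @export
compute_density <- function(x, sigma, metric = "L1") {
  .assert_positive(sigma, "sigma")
  v <- .values(x)
  structure(list(density = density_count_cpp(v, sigma, .metric_code(metric)),
                 sigma = sigma),
            class = "density_profile")
}

#' Suggest a density scale from the distance distribution
#'
#' Helps choose the density radius `sigma`: computes nearest-neighbour
#' distances on a random subsample and returns five times their median
#' (the SPADE convention), with the subsample's nearest-neighbour and
#' pairwise distance quantiles attached for inspection.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param metric distance metric.
#' @param n_sample subsample size used to estimate the distance
#'   distribution (the full pairwise computation is quadratic).
#' @param seed RNG seed for the subsample.
#' @param details also attach nearest-neighbour and pairwise distance
#'   quantiles as attribute `"quantiles"` for inspection.
#' @return Suggested sigma (numeric scalar).
#' @export
suggest_sigma <- function(x, metric = "L1", n_sample = 2000, seed = NULL,
                          details = FALSE) {
  v <- .values(x)
  n <- nrow(v)
  idx <- if (n > n_sample) .with_seed(seed, sample.int(n, n_sample)) else seq_len(n)
  D <- .cross_dist(v[idx, , drop = FALSE], metric = metric)
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  sigma <- 5 * stats::median(nn)
  if (sigma <= 0) sigma <- stats::median(D[is.finite(D)]) / 10
  if (!is.finite(sigma) || sigma <= 0)
    stop("cannot suggest sigma: degenerate distance distribution")
  if (details) {
    probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
    attr(sigma, "quantiles") <-
      list(nearest_neighbour = quantile(nn, probs),
           pairwise = quantile(D[is.finite(D)], probs))
  }
  sigma
}

#' Density-based downsampling and outlier removal
#'
#' Splits cells into three disjoint sets. Cells whose density falls below
#' the `outlier_percentile` density OD are outliers, permanently excluded
#' (they can create shortcut edges). Cells with density above the
#' `target_percentile` density TD are retained with probability
#' `TD / density` and downsampled otherwise, equalizing density across
#' state space so reference nodes are not biased toward dense regions.
#' Downsampled cells are excluded from node selection but re-included
#' for the Voronoi tessellation.
#'
#' @param density a `density_profile` from [compute_density()], or a
#'   numeric density vector.
#' @param outlier_percentile percentile (0-100) defining the outlier
#'   density cutoff; must be below `target_percentile`.
#' @param target_percentile percentile (0-100) defining the target
#'   density TD.
#' @param seed RNG seed; the stochastic keep/downsample decisions are
#'   reproducible given the seed.
#' @return A `downsample_result`: list of disjoint index sets `kept`,
#'   `downsampled`, `outliers` whose union is all cells.
#' @export
density_downsample <- function(density, outlier_percentile = 1,
                               target_percentile = 5, seed = NULL) {
  d <- if (inherits(density, "density_profile")) density$density else density
  d <- as.numeric(d)
  if (outlier_percentile < 0 || target_percentile > 100 ||
      outlier_percentile >= target_percentile)
    stop("need 0 <= outlier_percentile < target_percentile <= 100")
  od <- quantile(d, outlier_percentile / 100, names = FALSE)
  td <- quantile(d, target_percentile / 100, names = FALSE)
  outliers <- which(d < od)
  keep_prob <- ifelse(d > td, td / d, 1)
  u <- .with_seed(seed, runif(length(d)))
  downsampled <- setdiff(which(u > keep_prob), outliers)
  kept <- setdiff(seq_along(d), union(outliers, downsampled))
  structure(list(kept = kept, downsampled = downsampled, outliers = outliers),
            class = "downsample_result")
}

#' Diffusion-map embedding
#'
#' Classic diffusion maps: a Gaussian kernel
#' `W_ij = exp(-d_ij^2 / (2 sigma^2))` on Euclidean distances, row-sum
#' normalized to a Markov matrix whose spectrum is computed through the
#' symmetric conjugate. The trivial constant eigenvector (eigenvalue 1)
#' is dropped; components are returned in order of decreasing eigenvalue
#' and scaled by their eigenvalues. Well-separated mixture components map
#' onto approximately orthogonal diffusion components, which is why the
#' leading components are a good input space for branch analysis.
#'
#' Dense eigendecomposition: quadratic memory and cubic time in the
#' number of cells, intended for datasets up to a few thousand cells.
#'
#' @param x a [cell_matrix()] or numeric matrix.
#' @param n_components number of nontrivial components to return
#'   (must be smaller than the number of cells).
#' @param kernel_sigma Gaussian kernel bandwidth; default is the median
#'   pairwise Euclidean distance.
#' @return List with `embedding` (cells x n_components) and `eigenvalues`
#'   (non-increasing, one per returned component).
#' @export
diffusion_map <- function(x, n_components = 10, kernel_sigma = NULL) {
  v <- .values(x)
  n <- nrow(v)
  if (n_components >= n) stop("n_components must be smaller than the number of cells")
  D <- .cross_dist(v, metric = "L2")
  if (is.null(kernel_sigma)) kernel_sigma <- stats::median(D[upper.tri(D)])
  .assert_positive(kernel_sigma, "kernel_sigma")
  W <- exp(-D^2 / (2 * kernel_sigma^2))
  deg <- rowSums(W)
  s <- 1 / sqrt(deg)
  A <- W * tcrossprod(s)            # D^{-1/2} W D^{-1/2}
  eig <- eigen(A, symmetric = TRUE)
  lambda <- eig$values
  if (sum(lambda > 1 - 1e-8) > 1)
    warning("kernel graph appears disconnected; diffusion components may be degenerate")
  idx <- seq_len(n_components) + 1L   # drop the trivial first eigenvector
  # right eigenvectors of the Markov matrix, scaled by eigenvalue
  emb <- (s * eig$vectors[, idx, drop = FALSE]) *
    rep(lambda[idx], each = n)
  colnames(emb) <- paste0("DC", seq_len(n_components))
  list(embedding = emb, eigenvalues = lambda[idx])
}

#' Choose the number of components by the eigenvalue elbow
#'
#' Returns the position of the largest consecutive eigen-gap
#' `eigenvalue[i] - eigenvalue[i+1]` (ties broken toward the smallest
#' position). A user override is always possible by passing an explicit
#' component count to the pipeline.
#'
#' @param eigenvalues numeric vector of at least 3 eigenvalues, in
#'   non-increasing order.
#' @return Number of components to retain (positive integer).
#' @export
elbow_components <- function(eigenvalues) {
  if (length(eigenvalues) < 3) stop("need at least 3 eigenvalues")
  gaps <- -diff(eigenvalues)
  which.max(gaps)   # which.max takes the first maximum: smallest i on ties
}
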