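#' The reference parameter grid
#'
#' Grid of dataset- and analysis-specific parameters over which reference
#' score distributions are precomputed: number of cells
#' `n_obs = 10,000 ... 100,000` (step 10,000), dimensionality
#' `d = 5, 10, 15, 20, 25, 30`, reference nodes `k = 50, 100, 150, 200`,
#' noise `rho = 0` (noise-free non-branching data score highest, so the
#' noise-free reference is the conservative choice when the true noise
#' level is unknown). 240 combinations in total.
#'
#' @return data.frame with columns `n_obs`, `d`, `k`, `rho`.
#' @export
reference_grid <- function() {
  expand.grid(n_obs = seq(10000, 100000, by = 10000),
              d = c(5, 10, 15, 20, 25, 30),
              k = c(50, 100, 150, 200),
              rho = 0)
}

#' Generate a non-branching triangular reference dataset
#'
#' Uniform samples from a filled equilateral triangle (side 1, centred at
#' the origin), embedded in `d` dimensions (the first two coordinates
#' carry the triangle, the rest are zero), plus isotropic Gaussian noise
#' of standard deviation `rho` in all `d` dimensions. Among simple
#' convex (hence non-branching) 2-D manifolds, triangles produce the
#' highest raw branching scores, which makes them the conservative
#' reference topology. The whole pipeline is scale- and rigid-motion
#' invariant (distances plus a data-adaptive density radius), so the
#' shape normalization is the only free choice.
#'
#' @param n_obs number of cells.
#' @param d embedding dimensionality (at least 2).
#' @param rho noise standard deviation (the reference grid uses 0).
#' @param seed RNG seed.
#' @return A [cell_matrix()].
#' @export
generate_triangle_dataset <- function(n_obs, d = 5, rho = 0, seed = NULL) {
  if (d < 2) stop("d must be at least 2")
  .with_seed(seed, {
    # vertices of an equilateral side-1 triangle centred at the origin
    A <- c(-0.5, -sqrt(3) / 6); Bv <- c(0.5, -sqrt(3) / 6); C <- c(0, sqrt(3) / 3)
    r1 <- sqrt(runif(n_obs)); r2 <- runif(n_obs)
    xy <- outer(1 - r1, A) + outer(r1 * (1 - r2), Bv) + outer(r1 * r2, C)
    v <- matrix(0, n_obs, d)
    v[, 1:2] <- xy
    if (rho > 0) v <- v + matrix(rnorm(n_obs * d, sd = rho), n_obs, d)
    cell_matrix(v)
  })
}

#' Build a reference score distribution for one parameter combination
#'
#' Runs the full raw-score pipeline (density downsampling, node
#' selection, tree ensemble, per-node scoring) on `n_reps` independently
#' generated triangular datasets with the given parameters, records the
#' maximum raw branching score of each, and takes the 95th percentile
#' (linear interpolation between order statistics, quantile type 7) as
#' `b_ref`.
#'
#' @param n_obs,d,k,rho dataset/analysis parameters (see
#'   [reference_grid()]).
#' @param n_reps number of synthetic replicates (100 by default;
#'   1000 for a full-scale table).
#' @param config a [treetop_config()] supplying sigma/downsampling/
#'   ensemble settings for the runs; its `k` is overridden.
#' @param seed RNG seed; replicate seeds are derived as `seed + rep`.
#' @return A `reference_distribution`: list with `params`, `max_scores`,
#'   `b_ref`, `n_reps`.
#' @export
build_reference_distribution <- function(n_obs, d, k, rho = 0, n_reps = 100,
                                         config = treetop_config(),
                                         seed = NULL) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  config$k <- k
  max_scores <- vapply(seq_len(n_reps), function(r) {
    rs <- if (is.null(seed)) NULL else seed + r
    x <- generate_triangle_dataset(n_obs, d = d, rho = rho, seed = rs)
    res <- .treetop_raw(x, config, seed = rs)
    max(res$raw_scores)
  }, numeric(1))
  structure(list(params = list(n_obs = n_obs, d = d, k = k, rho = rho),
                 max_scores = max_scores,
                 b_ref = quantile(max_scores, 0.95, names = FALSE, type = 7),
                 n_reps = n_reps),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat("<reference_distribution> n_obs =", x$params$n_obs, "d =", x$params$d,
      "k =", x$params$k, "| b_ref =", format(x$b_ref, digits = 4),
      "(", x$n_reps, "reps )\n")
  invisible(x)
}

#' Build a reference lookup table
#'
#' Convenience wrapper building [build_reference_distribution()] for each
#' row of a parameter data.frame.
#'
#' @param params data.frame with columns `n_obs`, `d`, `k` (and
#'   optionally `rho`); e.g. a subset of [reference_grid()].
#' @inheritParams build_reference_distribution
#' @return A `reference_table`: list of `reference_distribution`s.
#' @export
build_reference_table <- function(params, n_reps = 100,
                                  config = treetop_config(), seed = NULL) {
  cells <- lapply(seq_len(nrow(params)), function(r) {
    build_reference_distribution(
      n_obs = params$n_obs[r], d = params$d[r], k = params$k[r],
      rho = if ("rho" %in% names(params)) params$rho[r] else 0,
      n_reps = n_reps, config = config,
      seed = if (is.null(seed)) NULL else seed + 10000L * r)
  })
  structure(cells, class = "reference_table")
}

#' Look up the reference distribution closest to a dataset
#'
#' Chooses the grid cell minimizing Euclidean distance to
#' `(n_obs, d, k)` after normalizing each axis by its canonical grid
#' range; ties are broken toward the cell with the larger `b_ref` (the
#' more conservative choice). Queries outside the grid ranges trigger a
#' warning and use the nearest edge cell; in particular the grid floor
#' `n_obs = 10,000` stands in for smaller datasets (branch analysis
#' refuses fewer than 1,000 cells anyway).
#'
#' @param table a `reference_table` (or list of
#'   `reference_distribution`s).
#' @param n_obs,d,k query parameters.
#' @return The selected `reference_distribution`.
#' @export
lookup_reference <- function(table, n_obs, d, k) {
  if (length(table) == 0) stop("empty reference table")
  ranges <- list(n_obs = c(10000, 100000), d = c(5, 30), k = c(50, 200))
  q <- c(n_obs = n_obs, d = d, k = k)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(q < lo) || any(q > hi))
    warning("query (n_obs = ", n_obs, ", d = ", d, ", k = ", k,
            ") lies outside the reference grid; using the nearest edge cell")
  scale <- hi - lo
  dist2 <- vapply(table, function(cell) {
    p <- c(cell$params$n_obs, cell$params$d, cell$params$k)
    sum(((q - p) / scale)^2)
  }, numeric(1))
  brefs <- vapply(table, function(cell) cell$b_ref, numeric(1))
  cand <- which(dist2 <= min(dist2) + 1e-12)
  table[[cand[which.max(brefs[cand])]]]
}

#' Relative branching score
#'
#' The maximum raw branching score of the input divided by `b_ref`, the
#' 95th percentile of maximum raw scores in the matched non-branching
#' reference distribution. Values above 1 indicate more branching than
#' any simple non-branching topology produces; values at or below 1
#' indicate no, or weak, evidence of branching.
#'
#' @param b_max maximum raw branching score of the input dataset.
#' @param b_ref reference 95th percentile (must be positive), or a
#'   `reference_distribution`.
#' @return The ratio `b_max / b_ref`.
#' @export
relative_score <- function(b_max, b_ref) {
  if (inherits(b_ref, "reference_distribution")) b_ref <- b_ref$b_ref
  if (!is.finite(b_ref) || b_ref <= 0)
    stop("b_ref must be positive (degenerate reference distribution)")
  b_max / b_ref
}

#' Write a reference table to a directory of CSV files
#'
#' One CSV per grid cell (`ref_nobs<k>_d<d>_k<k>.csv`) holding the
#' parameters and one max score per row, plus an `index.csv`; the pair
#' of [write_reference_table()] and [read_reference_table()] round-trips
#' a table exactly.
#'
#' @param table a `reference_table`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the index data.frame.
#' @export
write_reference_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(table, function(cell) {
    p <- cell$params
    fn <- sprintf("ref_nobs%d_d%d_k%d.csv", p$n_obs, p$d, p$k)
    data.table::fwrite(data.frame(n_obs = p$n_obs, d = p$d, k = p$k,
                                  rho = p$rho, max_score = cell$max_scores),
                       file.path(dir, fn))
    data.frame(file = fn, n_obs = p$n_obs, d = p$d, k = p$k, rho = p$rho,
               n_reps = cell$n_reps, b_ref = cell$b_ref)
  }))
  data.table::fwrite(idx, file.path(dir, "index.csv"))
  invisible(idx)
}

#' Read a reference table written by [write_reference_table()]
#'
#' @param dir directory holding `index.csv` and the per-cell CSVs.
#' @return A `reference_table`.
#' @export
read_reference_table <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) stop("no index.csv under ", dir)
  idx <- data.table::fread(idx_path, data.table = FALSE)
  cells <- lapply(seq_len(nrow(idx)), function(r) {
    dat <- data.table::fread(file.path(dir, idx$file[r]), data.table = FALSE)
    structure(list(params = list(n_obs = idx$n_obs[r], d = idx$d[r],
                                 k = idx$k[r], rho = idx$rho[r]),
                   max_scores = dat$max_score,
                   b_ref = quantile(dat$max_score, 0.95, names = FALSE),
                   n_reps = nrow(dat)),
              class = "reference_distribution")
  })
  structure(cells, class = "reference_table")
}
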