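#' Hill-kinetics production propensity of a toggle-switch protein
#'
#' A protein is produced when activated from upstream and not inhibited
#' by its switch partner:
#' `alpha * gU^h+ / (gU^h+ + kappa+^h+) * kappa-^h- / (gS^h- + kappa-^h-)`.
#' Root proteins have no upstream activator; their activation term is 1.
#' The propensity lies in `[0, alpha]`.
#'
#' @param g_U upstream activator count (ignored when `root = TRUE`).
#' @param g_S switch-partner count.
#' @param params list with `alpha` (basal production rate), `kappa_act`,
#'   `h_act` (activation dissociation constant and Hill coefficient),
#'   `kappa_inh`, `h_inh` (inhibition counterparts); all positive.
#' @param root logical; `TRUE` for proteins with constitutive activation.
#' @return Nonnegative production propensity (vectorized over counts).
#' @export
production_propensity <- function(g_U, g_S, params, root = FALSE) {
  act <- if (root) 1 else {
    gu <- g_U^params$h_act
    gu / (gu + params$kappa_act^params$h_act)
  }
  gs <- g_S^params$h_inh
  ki <- params$kappa_inh^params$h_inh
  params$alpha * act * ki / (gs + ki)
}

#' Mass-action degradation propensity
#'
#' @param g protein count (nonnegative).
#' @param delta degradation rate constant.
#' @return `delta * g`.
#' @export
degradation_propensity <- function(g, delta) delta * g

#' Build a hierarchical toggle-switch model
#'
#' A complete binary tree of mutually inhibiting protein pairs
#' ("switches"): the root switch's two proteins each activate one
#' downstream switch, and so on to the given depth, giving
#' `2^(depth+1) - 2` proteins. Each trajectory commits stochastically
#' and mutually exclusively to one protein per switch along its realized
#' path, mimicking a multi-step differentiation cascade.
#'
#' The default rates make each switch bistable in the deterministic
#' limit and commit well within the default simulation horizon:
#' `alpha = 40`, `delta = 0.1` (winner steady state
#' `alpha/delta = 400`), inhibition `kappa_inh = 5`, `h_inh = 4` (sharp
#' mutual repression, so the symmetric race state is strongly unstable
#' and losers settle far below winners), activation `kappa_act = 200`,
#' `h_act = 4` (a switch only engages once its upstream activator is
#' near its winning steady state, so successive fate decisions are
#' separated in time, as in real differentiation cascades, and the
#' intermediate "trunk" states stay populated in snapshot data). A full
#' parameter list can be supplied instead.
#'
#' @param depth number of switch levels (1 = a single binary switch).
#' @param params named list of rate parameters, see
#'   [production_propensity()] plus `delta`; each element may be a
#'   scalar (shared by all proteins) or a vector of per-species values.
#' @param level_scale factor by which `alpha` and `delta` are multiplied
#'   per switch level below the root (winner steady state `alpha/delta`
#'   is unchanged). Values below 1 slow deeper switches down, separating
#'   successive fate decisions in time the way real differentiation
#'   cascades do; this keeps the intermediate (trunk) states populated
#'   so the hierarchy is visible in snapshot data. Ignored for elements
#'   of `params` passed as per-species vectors.
#' @return A `toggle_switch_model`: list with `n_species`, `upstream`
#'   (`NA` for the two root proteins), `partner`, `params` (all expanded
#'   to per-species vectors).
#' @export
build_hierarchy_model <- function(depth,
                                  params = list(alpha = 40, delta = 0.1,
                                                kappa_act = 200, h_act = 4,
                                                kappa_inh = 5, h_inh = 4),
                                  level_scale = 1) {
  if (depth < 1) stop("depth must be at least 1")
  n_species <- 2L^(depth + 1L) - 2L
  s <- seq_len(n_species)
  upstream <- ifelse(s <= 2, NA_integer_, (s - 1L) %/% 2L)
  partner <- ifelse(s %% 2L == 1L, s + 1L, s - 1L)
  partner[1:2] <- c(2L, 1L)
  level <- floor(log2(s + 1))
  stopifnot(all(unlist(params) > 0), level_scale > 0)
  expand <- function(p, scaled) {
    if (length(p) == n_species) return(as.numeric(p))
    if (length(p) != 1) stop("parameter must be scalar or one value per species")
    if (scaled) p * level_scale^(level - 1) else rep(p, n_species)
  }
  params <- list(alpha = expand(params$alpha, TRUE),
                 delta = expand(params$delta, TRUE),
                 kappa_act = expand(params$kappa_act, FALSE),
                 h_act = expand(params$h_act, FALSE),
                 kappa_inh = expand(params$kappa_inh, FALSE),
                 h_inh = expand(params$h_inh, FALSE))
  structure(list(n_species = n_species, upstream = as.integer(upstream),
                 partner = as.integer(partner), params = params,
                 level = level, depth = depth),
            class = "toggle_switch_model")
}

#' Simulate the toggle-switch cascade by tau-leaping
#'
#' Fixed-step tau-leaping: every step advances each production and
#' degradation reaction by a Poisson-distributed event count with mean
#' `propensity * dt`; negative excursions are clamped to zero. Initial
#' counts are Poisson(`lambda_init`) per protein, and states are saved
#' at `n_timepoints` uniform times from 0 to `t_end`. The default step
#' is chosen so the largest expected propensity advances only a few
#' events per step. Accuracy check: at each step the propensities are
#' re-evaluated at the deterministic one-step prediction; if this
#' drift-induced change exceeds 10% (90th percentile over reactions with
#' propensity above 1), the step is too large for the leap approximation
#' and a warning is raised. (Propensity swings caused by intrinsic
#' single-molecule noise near sharp Hill thresholds are not step-size
#' error and do not trigger it.)
#'
#' @param model a [build_hierarchy_model()].
#' @param n_traj number of trajectories (cells); the desk-scale default
#'   is 2000, large-scale studies would use many more.
#' @param t_end simulation horizon.
#' @param n_timepoints number of uniformly placed save points.
#' @param lambda_init Poisson mean of the initial counts.
#' @param dt tau-leap step; `NULL` chooses automatically.
#' @param seed RNG seed.
#' @return A `simulation_run`: list with `counts`
#'   (`n_traj x n_timepoints x n_species` array of nonnegative integer
#'   counts), `times`, `model`, `seed`.
#' @export
tau_leap_simulate <- function(model, n_traj = 2000, t_end = 150, n_timepoints = 100,
                              lambda_init = 100, dt = NULL, seed = NULL) {
  .assert_positive(t_end, "t_end")
  .assert_positive(lambda_init, "lambda_init")
  ns <- model$n_species
  p <- lapply(model$params, function(e) if (length(e) == 1) rep(e, ns) else e)
  if (is.null(dt)) {
    a_max <- max(max(p$alpha), max(p$delta) * 3 * lambda_init)
    dt <- min(5 / a_max, t_end / n_timepoints)
  }
  .assert_positive(dt, "dt")
  times <- seq(0, t_end, length.out = n_timepoints)
  roots <- is.na(model$upstream)
  p_s <- lapply(seq_len(ns), function(s) lapply(p, `[`, s))
  prop <- function(M) {
    P <- matrix(0, nrow(M), ns)
    for (s in seq_len(ns)) {
      P[, s] <- production_propensity(
        g_U = if (roots[s]) NULL else M[, model$upstream[s]],
        g_S = M[, model$partner[s]], params = p_s[[s]], root = roots[s])
    }
    P
  }
  .with_seed(seed, {
    M <- matrix(rpois(n_traj * ns, lambda_init), n_traj, ns)
    counts <- array(0L, dim = c(n_traj, n_timepoints, ns))
    counts[, 1, ] <- M
    t_now <- 0
    max_rel_change <- 0
    a_prev <- prop(M)
    deg_rate <- function(M) sweep(M, 2, p$delta, "*")
    for (ti in 2:n_timepoints) {
      while (t_now < times[ti] - 1e-12) {
        step <- min(dt, times[ti] - t_now)
        # drift-induced propensity change over one step (leap accuracy)
        M_drift <- pmax(M + (a_prev - deg_rate(M)) * step, 0)
        a_drift <- prop(M_drift)
        big <- a_prev > 1
        if (any(big)) {
          rel <- abs(a_drift[big] - a_prev[big]) / a_prev[big]
          max_rel_change <- max(max_rel_change, stats::quantile(rel, 0.9))
        }
        births <- matrix(rpois(n_traj * ns, a_prev * step), n_traj, ns)
        deaths <- matrix(rpois(n_traj * ns, deg_rate(M) * step), n_traj, ns)
        M <- pmax(M + births - deaths, 0)
        t_now <- t_now + step
        a_prev <- prop(M)
      }
      counts[, ti, ] <- M
    }
    if (max_rel_change > 0.1)
      warning("tau-leap step may be too large: propensities changed by ",
              round(100 * max_rel_change), "% within a step; reduce dt")
    structure(list(counts = counts, times = times, model = model, seed = seed),
              class = "simulation_run")
  })
}

#' Flatten a simulation into a single-cell snapshot matrix
#'
#' Samples `(trajectory, timepoint)` pairs uniformly without replacement
#' and attaches a ground-truth fate label to each sampled cell: starting
#' at the root switch, the committed arm is the protein with the higher
#' count, descending while the switch is decided (winner at least
#' `decided_ratio` times the loser, counting from 1); the label is the
#' `/`-separated path of winning species, or `"undecided"` before root
#' commitment.
#'
#' @param run a `simulation_run`.
#' @param n_cells number of cells to draw (at most
#'   `n_traj * n_timepoints`).
#' @param decided_ratio fold change declaring a switch decided.
#' @param seed RNG seed.
#' @return A [cell_matrix()] with species `g1..gN`, labels as above, and
#'   the root-level winner in `$label_root`.
#' @export
sample_cells_from_run <- function(run, n_cells, decided_ratio = 5, seed = NULL) {
  dims <- dim(run$counts)
  n_pairs <- dims[1] * dims[2]
  if (n_cells > n_pairs)
    stop("cannot sample ", n_cells, " cells from ", n_pairs,
         " (trajectory, timepoint) pairs")
  model <- run$model
  idx <- .with_seed(seed, sample.int(n_pairs, n_cells))
  traj <- (idx - 1L) %% dims[1] + 1L
  tp <- (idx - 1L) %/% dims[1] + 1L
  v <- matrix(0, n_cells, dims[3])
  for (s in seq_len(dims[3])) v[, s] <- run$counts[cbind(traj, tp, s)]
  colnames(v) <- paste0("g", seq_len(dims[3]))
  decided <- function(a, b) max(a, b) >= decided_ratio * (min(a, b) + 1)
  label_one <- function(counts) {
    a <- 1L; b <- 2L
    if (!decided(counts[a], counts[b])) return("undecided")
    path <- integer(0)
    repeat {
      win <- if (counts[a] >= counts[b]) a else b
      path <- c(path, win)
      ca <- 2L * win + 1L
      if (ca + 1L > model$n_species) break
      a <- ca; b <- ca + 1L
      if (!decided(counts[a], counts[b])) break
    }
    paste(path, collapse = "/")
  }
  labels <- apply(v, 1, label_one)
  out <- cell_matrix(v, labels = labels)
  out$label_root <- vapply(strsplit(labels, "/"), `[`, character(1), 1)
  out
}

#' Generate simple geometric synthetic datasets
#'
#' Uniform samples on named low-dimensional manifolds embedded in `d`
#' dimensions (the manifold occupies the first coordinates, the rest are
#' zero), plus isotropic Gaussian noise of standard deviation `rho` in
#' all dimensions:
#' * `path` - unit segment (1-D, non-branching);
#' * `circle` - unit-radius circumference (1-D with a cycle);
#' * `triangle` - filled equilateral triangle, see
#'   [generate_triangle_dataset()] (2-D, non-branching);
#' * `blob` - isotropic Gaussian in all `d` dimensions (a 0-D manifold
#'   consisting of pure measurement spread; SD `rho`, or 1 when
#'   `rho = 0`);
#' * `star` - `arms` unit-length rays from the origin at equal angles
#'   (the branching positive control; ground-truth arm labels attached).
#'
#' @param kind one of `"path"`, `"star"`, `"circle"`, `"blob"`,
#'   `"triangle"`.
#' @param n_obs number of cells.
#' @param d embedding dimensionality (at least 2).
#' @param rho noise standard deviation.
#' @param arms number of star arms.
#' @param arm_length star arm length.
#' @param seed RNG seed.
#' @return A [cell_matrix()]; for `star`, labels hold the arm index.
#' @export
generate_geometry <- function(kind = c("path", "star", "circle", "blob", "triangle"),
                              n_obs, d = 5, rho = 0, arms = 3, arm_length = 1,
                              seed = NULL) {
  kind <- match.arg(kind)
  if (d < 2) stop("d must be at least 2")
  if (kind == "triangle")
    return(generate_triangle_dataset(n_obs, d = d, rho = rho, seed = seed))
  .with_seed(seed, {
    v <- matrix(0, n_obs, d)
    labels <- NULL
    if (kind == "path") {
      v[, 1] <- runif(n_obs)
    } else if (kind == "circle") {
      th <- runif(n_obs, 0, 2 * pi)
      v[, 1] <- cos(th); v[, 2] <- sin(th)
    } else if (kind == "blob") {
      # pure isotropic spread; rho is the whole signal, so no extra noise
      sd_blob <- if (rho > 0) rho else 1
      v <- matrix(rnorm(n_obs * d, sd = sd_blob), n_obs, d)
      rho <- 0
    } else if (kind == "star") {
      arm <- sample.int(arms, n_obs, replace = TRUE)
      r <- runif(n_obs, 0, arm_length)
      th <- 2 * pi * (arm - 1) / arms
      v[, 1] <- r * cos(th); v[, 2] <- r * sin(th)
      labels <- as.character(arm)
    }
    if (rho > 0) v <- v + matrix(rnorm(n_obs * d, sd = rho), n_obs, d)
    cell_matrix(v, labels = labels)
  })
}
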