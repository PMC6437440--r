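default_params <- function() list(alpha = 40, delta = 0.1, kappa_act = 200,
                                  h_act = 4, kappa_inh = 5, h_inh = 4)

test_that("production propensity follows the Hill activation-inhibition product", {
  p <- list(alpha = 5, delta = 0.05, kappa_act = 50, h_act = 2,
            kappa_inh = 30, h_inh = 2)
  expect_equal(production_propensity(0, 10, p), 0)
  # full activation, no inhibition -> alpha
  expect_equal(production_propensity(1e9, 0, p), p$alpha, tolerance = 1e-6)
  # both Hill terms at their dissociation constants -> alpha / 4
  for (h in c(1, 2, 4)) {
    ph <- p; ph$h_act <- h; ph$h_inh <- h
    expect_equal(production_propensity(ph$kappa_act, ph$kappa_inh, ph),
                 p$alpha / 4)
  }
  # bounded by alpha
  g <- expand.grid(u = c(0, 10, 100, 1000), s = c(0, 10, 100, 1000))
  vals <- production_propensity(g$u, g$s, p)
  expect_true(all(vals >= 0 & vals <= p$alpha))
  # root proteins: activation term is 1
  expect_equal(production_propensity(NULL, 0, p, root = TRUE), p$alpha)
})

test_that("degradation is mass-action", {
  expect_equal(degradation_propensity(0, 0.1), 0)
  expect_equal(degradation_propensity(100, 0.01), 1)
  g <- 0:50
  expect_equal(degradation_propensity(g, 0.3), 0.3 * g)
})

test_that("hierarchy models wire a complete binary tree of switches", {
  m1 <- build_hierarchy_model(1)
  expect_equal(m1$n_species, 2)
  expect_equal(m1$partner, c(2L, 1L))
  expect_true(all(is.na(m1$upstream)))
  m2 <- build_hierarchy_model(2)
  expect_equal(m2$n_species, 6)
  expect_equal(m2$upstream, c(NA, NA, 1L, 1L, 2L, 2L))
  m3 <- build_hierarchy_model(3)
  expect_equal(m3$n_species, 14)
  # partners are mutual and every non-root activator is in the parent switch
  for (m in list(m2, m3)) {
    expect_equal(m$partner[m$partner], seq_len(m$n_species))
    nonroot <- which(!is.na(m$upstream))
    for (s in nonroot) {
      parent <- m$upstream[s]
      expect_equal(m$upstream[m$partner[s]], parent)  # same switch, same activator
      expect_equal(m$level[s], m$level[parent] + 1)
    }
  }
  expect_error(build_hierarchy_model(0), "at least 1")
})

test_that("tau-leap death process matches the exponential mean", {
  # alpha ~ 0: pure death from Poisson(100), mean lambda * exp(-delta t)
  p <- default_params()
  p$alpha <- 1e-9
  model <- build_hierarchy_model(1, params = p)
  run <- tau_leap_simulate(model, n_traj = 500, t_end = 30, n_timepoints = 31,
                           lambda_init = 100, dt = 0.1, seed = 6)
  for (tp in c(11, 21, 31)) {
    t_at <- run$times[tp]
    expected <- 100 * exp(-p$delta * t_at)
    obs <- run$counts[, tp, 1]
    se <- sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - expected), 3 * se + 0.05 * expected)
  }
  expect_true(all(run$counts >= 0))
})

test_that("tau-leap growth without regulation follows lambda + alpha t", {
  # delta ~ 0 and saturated activation: mean grows linearly
  p <- default_params()
  p$delta <- 1e-9
  p$kappa_inh <- 1e6   # effectively no inhibition at these counts
  model <- build_hierarchy_model(1, params = p)
  run <- tau_leap_simulate(model, n_traj = 400, t_end = 10, n_timepoints = 11,
                           lambda_init = 100, dt = 0.05, seed = 7)
  obs <- run$counts[, 11, 1]
  expected <- 100 + p$alpha * 10
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.02 * expected)
})

test_that("simulations are reproducible and warn on oversized steps", {
  model <- build_hierarchy_model(1)
  r1 <- tau_leap_simulate(model, n_traj = 50, t_end = 20, seed = 8)
  r2 <- tau_leap_simulate(model, n_traj = 50, t_end = 20, seed = 8)
  expect_identical(r1$counts, r2$counts)
  expect_warning(tau_leap_simulate(model, n_traj = 50, t_end = 50, dt = 5,
                                   seed = 8), "too large")
})

test_that("switches commit mutually exclusively and both root fates occur", {
  model <- build_hierarchy_model(2)
  run <- tau_leap_simulate(model, n_traj = 1000, seed = 9)
  final <- run$counts[, 100, ]
  # root switch: winner at least 5x loser in at least 95% of trajectories
  ratio_root <- pmax(final[, 1], final[, 2]) / (pmin(final[, 1], final[, 2]) + 1)
  expect_gte(mean(ratio_root > 5), 0.95)
  # child switch on the realized path, same criterion
  win1 <- final[, 1] > final[, 2]
  pair <- ifelse(win1, 3L, 5L)
  ca <- final[cbind(seq_len(1000), pair)]
  cb <- final[cbind(seq_len(1000), pair + 1L)]
  expect_gte(mean(pmax(ca, cb) / (pmin(ca, cb) + 1) > 5), 0.95)
  # both root arms taken in at least 20% of trajectories
  expect_gte(mean(win1), 0.2)
  expect_gte(mean(!win1), 0.2)
})

test_that("sampled cells flatten the run with consistent fate labels", {
  model <- build_hierarchy_model(1)
  run <- tau_leap_simulate(model, n_traj = 40, t_end = 100, n_timepoints = 20,
                           seed = 10)
  # sampling all pairs gives the full flattening
  x_all <- sample_cells_from_run(run, n_cells = 40 * 20, seed = 11)
  expect_equal(nrow(x_all$values), 800)
  expect_error(sample_cells_from_run(run, n_cells = 801), "cannot sample")
  # labels are deterministic given counts
  x_b <- sample_cells_from_run(run, n_cells = 200, seed = 12)
  x_c <- sample_cells_from_run(run, n_cells = 200, seed = 12)
  expect_identical(x_b$labels, x_c$labels)
  # late-timepoint cells are committed with exactly one high protein per switch
  late <- run$counts[, 20, ]
  ratio <- pmax(late[, 1], late[, 2]) / (pmin(late[, 1], late[, 2]) + 1)
  expect_gte(mean(ratio > 5), 0.95)
  lab <- x_b$labels
  committed <- lab != "undecided"
  expect_true(all(lab[committed] %in% c("1", "2")))
})

test_that("geometric generators place points on the named manifolds", {
  circ <- generate_geometry("circle", 500, d = 4, seed = 13)
  radii <- sqrt(rowSums(circ$values[, 1:2]^2))
  expect_equal(radii, rep(1, 500), tolerance = 1e-9)
  expect_equal(circ$values[, 3:4], matrix(0, 500, 2), ignore_attr = TRUE)
  blob <- generate_geometry("blob", 2000, d = 3, seed = 14)
  se <- 1 / sqrt(2000)
  expect_true(all(abs(colMeans(blob$values)) < 3 * se))
  expect_equal(unname(apply(blob$values, 2, sd)), rep(1, 3), tolerance = 0.1)
  star <- generate_geometry("star", 600, d = 2, arms = 3, seed = 15)
  expect_equal(sort(unique(star$labels)), c("1", "2", "3"))
  expect_true(all(sqrt(rowSums(star$values^2)) <= 1 + 1e-9))
  pth <- generate_geometry("path", 100, d = 2, seed = 16)
  expect_true(all(pth$values[, 1] >= 0 & pth$values[, 1] <= 1))
  expect_error(generate_geometry("path", 100, d = 1), "at least 2")
})
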