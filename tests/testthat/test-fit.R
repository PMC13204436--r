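test_that("noiseless high-count decays are recovered almost exactly", {
  shape <- expected_decay_shape(72.2, 0.4, 3.66, shared_irf, 0.01)
  h <- decay_histogram(shared_irf$bin_edges, round(shape * 2e6),
                       cell_id = "noiseless")
  fit <- fit_biexponential(h, shared_irf)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha1 - 72.2), 0.5)
  expect_lt(abs(fit$tau1 - 0.4), 0.02)
  expect_lt(abs(fit$tau2 - 3.66), 0.02)
  expect_lt(abs(fit$background - 0.01), 0.005)

  fit_ls <- fit_biexponential(h, shared_irf, method = "weighted_ls")
  expect_lt(abs(fit_ls$alpha1 - 72.2), 0.5)
  expect_lt(abs(fit_ls$tau2 - 3.66), 0.02)
})

test_that("a mono-exponential input yields a negligible second component", {
  h <- simulate_cell_decay(100, 0.4, 3.0, 5e4, irf = shared_irf, seed = 31)
  fit <- fit_biexponential(h, shared_irf)
  expect_lt(fit$alpha2, 2)
})

test_that("the compiled objective agrees with the independent oracle", {
  h <- simulate_cell_decay(65, 0.45, 3.1, 2000, irf = shared_irf64, seed = 1)
  ia <- shared_irf64$amplitudes / sum(shared_irf64$amplitudes)
  dt <- diff(h$bin_edges[1:2])
  for (th in list(c(65, 0.45, 3.1, 0.01, 0), c(40, 0.3, 2, 0.01, 0),
                  c(90, 0.8, 5, 0.01, 0))) {
    expect_equal(
      flimresponse:::cpp_decay_objective(th, as.numeric(h$counts), ia, dt,
                                         TRUE),
      oracle_nll(th[1], th[2], th[3], as.numeric(h$counts), shared_irf64,
                 bg = 0.01),
      tolerance = 1e-10)
  }
})

# background and shift held at the simulator values so the search spaces match
fixed_nuisance_options <- function() {
  opts <- default_fit_options()
  opts$lower["bg"] <- opts$upper["bg"] <- 0.01
  opts$fit_shift <- FALSE
  opts[c("lower", "upper", "fit_shift")]
}

test_that("the optimizer never loses to a coarse grid search", {
  for (i in 1:10) {
    set.seed(400 + i)
    a1 <- runif(1, 40, 90); t1 <- runif(1, 0.2, 0.7); t2 <- runif(1, 2, 4.5)
    h <- suppressWarnings(
      simulate_cell_decay(a1, t1, t2, 2000, irf = shared_irf64,
                          seed = 500 + i))
    fit <- fit_biexponential(h, shared_irf64, options = fixed_nuisance_options())
    grid_best <- oracle_grid_best(as.numeric(h$counts), shared_irf64)
    expect_lte(fit$objective, grid_best + 1e-6)
  }
})

test_that("estimator bias shrinks as the photon budget grows", {
  budgets <- c(1e3, 1e4, 1e5)
  bias_a1 <- bias_t2 <- numeric(3)
  for (b in seq_along(budgets)) {
    ests <- t(vapply(1:60, function(i) {
      h <- simulate_cell_decay(72.2, 0.4, 3.66, budgets[b], irf = shared_irf,
                               seed = 600 + 100 * b + i)
      f <- fit_biexponential(h, shared_irf)
      c(f$alpha1, f$tau2)
    }, numeric(2)))
    bias_a1[b] <- abs(mean(ests[, 1]) - 72.2)
    bias_t2[b] <- abs(mean(ests[, 2]) - 3.66)
  }
  expect_true(all(diff(bias_a1) < 0))
  expect_true(all(diff(bias_t2) < 0))
  expect_lt(bias_a1[3], 0.3)
  expect_lt(bias_t2[3], 0.03)
})

test_that("high-budget round trip recovers alpha1 within one point", {
  h <- simulate_cell_decay(72.2, 0.4, 3.66, 1e5, irf = shared_irf, seed = 77)
  fit <- fit_biexponential(h, shared_irf)
  expect_lt(abs(fit$alpha1 - 72.2), 1)
})

test_that("mean lifetime follows the amplitude-weighted formula", {
  expect_equal(mean_lifetime(100, 0.4, 3.66), 0.4)
  expect_equal(mean_lifetime(50, 1, 3), 2.0)
  # hand calculation: (72.2*0.4 + 27.8*3.66) / 100
  expect_equal(mean_lifetime(72.2, 0.4, 3.66), 1.30628)
  f <- fit_biexponential(
    simulate_cell_decay(70, 0.4, 3.2, 5000, irf = shared_irf, seed = 9),
    shared_irf)
  expect_equal(mean_lifetime(f), f$tau_m)
})

test_that("low-count cells are refused with a typed error", {
  h <- suppressWarnings(
    simulate_cell_decay(70, 0.4, 3.2, 80, irf = shared_irf, seed = 13))
  expect_error(fit_biexponential(h, shared_irf),
               class = "flim_low_count_error")
})

test_that("fit_sample applies QC and logs drops", {
  p <- population_params(70, 3, mean_tau2 = 3.2, sd_tau2 = 0.2, n_cells = 8,
                         photons_per_cell = 5000)
  arm <- simulate_arm(arm_spec("QC", "treated", 7, p, seed = 41),
                      irf = shared_irf)
  fits <- fit_sample(arm)
  expect_equal(nrow(fits), 8)
  expect_true(all(fits$qc_flag == "ok"))
  expect_fit_identities(fits)

  low <- suppressWarnings(lapply(1:3, function(i)
    simulate_cell_decay(70, 0.4, 3.2, 60, irf = shared_irf, seed = 50 + i,
                        cell_id = paste0("low", i))))
  fits2 <- fit_sample(c(arm$cells, low), irf = shared_irf)
  expect_equal(nrow(fits2), 8)
  expect_equal(unname(attr(fits2, "qc_log")["low_count"]), 3L,
               ignore_attr = TRUE)
  expect_error(fit_sample(low, irf = shared_irf), "empty sample")
  expect_error(fit_sample(low[1], irf = shared_irf))
})

test_that("fitted arm means recover the generating summary", {
  p <- params_from_summary(72.2, 0.7, 3.66, 0.05, n_cells = 35)
  arm <- suppressWarnings(
    simulate_arm(arm_spec("M5", "treated", 2, p, seed = 61),
                 irf = shared_irf))
  fits <- fit_arm(arm)
  expect_fit_identities(fits)
  # tolerances: ~2 standard errors of the arm mean, including the per-cell
  # fit noise on top of the population spread
  expect_lt(abs(mean(fits$alpha1) - 72.2), 1.5)
  expect_lt(abs(mean(fits$tau2) - 3.66), 0.15)
  # per-cell agreement with the generating truth
  expect_lt(abs(mean(fits$alpha1 - fits$true_alpha1)), 0.5)
  expect_lt(abs(mean(fits$tau2 - fits$true_tau2)), 0.08)
})
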