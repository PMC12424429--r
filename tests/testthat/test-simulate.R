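test_that("preset construction enforces the occupancy/dwell consistency", {
  p <- sim_preset(d_free = 0.5, trap_dwell_mean_s = 0.3, occupancy = 0.25)
  expect_equal(p$free_dwell_mean_s, 0.3 * 0.75 / 0.25)
  p2 <- sim_preset(d_free = 0.5, trap_dwell_mean_s = 0.3,
                   free_dwell_mean_s = 0.9)
  expect_equal(p2$occupancy, 0.25)
  expect_error(sim_preset(d_free = 0.5, trap_dwell_mean_s = 0.3,
                          occupancy = 0.5, free_dwell_mean_s = 0.9),
               "inconsistent")
  expect_error(sim_preset(d_free = 0.5, trap_dwell_mean_s = 0.3),
               "occupancy")
})

test_that("degenerate presets behave as advertised", {
  # occupancy 0: pure Brownian, no trapped frames
  p0 <- sim_preset(d_free = 0.53, occupancy = 0, trap_dwell_mean_s = 0.1,
                   n_cells = 1, trajectories_per_cell = 30)
  ts0 <- simulate_experiment(p0, seed = 4)
  expect_equal(true_occupancy(ts0), 0)

  # d_free 0 with occupancy 1: stationary emitter, spread is pure noise
  set.seed(2)
  p1 <- sim_preset(d_free = 0, occupancy = 1, trap_dwell_mean_s = 1,
                   trap_conf_sd_nm = 0, sigma_axis_nm = 14,
                   bleach_lifetime_s = Inf, movie_frames = 200)
  tr <- simulate_trajectory(p1)
  expect_equal(n_frames(tr), 200L)
  expect_equal(sd(tr$x), 0.014, tolerance = 0.15)
  expect_true(all(attr(tr, "trapped")))
})

test_that("free-state empirical MSD matches 4 D dt + 4 sigma^2 within 3%", {
  set.seed(99)
  d <- 0.53; sig <- 0.014; dt <- 1 / 30
  p <- sim_preset(d_free = d, occupancy = 0, trap_dwell_mean_s = 0.1,
                  sigma_axis_nm = 1000 * sig, bleach_lifetime_s = Inf,
                  movie_frames = 301, n_cells = 1, trajectories_per_cell = 40)
  ts <- simulate_experiment(p, seed = 99)
  msd1 <- vapply(ts$trajectories, function(tr) compute_msd(tr, 1)$msd, 1)
  expect_equal(mean(msd1), 4 * d * dt + 4 * sig^2,
               tolerance = 0.03)
})

test_that("simulations are reproducible from (preset, seed) and cells are independent", {
  p <- sim_preset(d_free = 0.3, trap_dwell_mean_s = 0.3, occupancy = 0.2,
                  n_cells = 4, trajectories_per_cell = 10)
  a <- simulate_experiment(p, seed = 123)
  b <- simulate_experiment(p, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c3 <- simulate_experiment(p, seed = 124)
  expect_false(identical(as.data.frame(a), as.data.frame(c3)))

  # per-cell means fluctuate with ~1/sqrt(n) SEM scaling
  set.seed(5)
  frac_sd <- function(tpc) {
    q <- sim_preset(d_free = 0.3, trap_dwell_mean_s = 0.3, occupancy = 0.2,
                    n_cells = 12, trajectories_per_cell = tpc)
    tsq <- simulate_experiment(q, seed = 7)
    cells <- vapply(tsq$trajectories, `[[`, "", "cell_id")
    occ <- vapply(tsq$trajectories, function(tr) mean(attr(tr, "trapped")), 1)
    sd(tapply(occ, cells, mean))
  }
  ratio <- frac_sd(10) / frac_sd(160)
  expect_gt(ratio, 2)   # expected 4, allow generous Monte Carlo slack
})

test_that("hidden-state occupancy converges to the preset occupancy", {
  p <- sim_preset(d_free = 0.4, trap_dwell_mean_s = 0.338, occupancy = 0.0888,
                  n_cells = 10, trajectories_per_cell = 120)
  ts <- simulate_experiment(p, seed = 17)
  expect_equal(true_occupancy(ts), p$occupancy, tolerance = 0.06)

  p2 <- sim_preset(d_free = 0.1, trap_dwell_mean_s = 0.1413, occupancy = 0.686,
                   n_cells = 10, trajectories_per_cell = 120)
  ts2 <- simulate_experiment(p2, seed = 18)
  expect_equal(true_occupancy(ts2), p2$occupancy, tolerance = 0.02)
})

test_that("the truncation oracles evaluate their closed forms", {
  dp <- trap_params()
  dt <- 1 / 30
  # threshold time T = 5 dt = 166.7 ms; tau = 338 ms gives ~0.912
  expect_equal(expected_detected_fraction(1, dp, dt = dt,
                                          trap_dwell_mean_s = 0.338),
               exp(-(5 * dt) / 0.338) * (1 + (5 * dt) / 0.338))
  expect_equal(expected_detected_fraction(1, dp, dt = dt,
                                          trap_dwell_mean_s = 0.338),
               0.912, tolerance = 1e-3)
  # tau = T gives 2/e; tau >> T approaches 1
  Tthr <- 5 * dt
  expect_equal(expected_detected_fraction(1, dp, dt = dt,
                                          trap_dwell_mean_s = Tthr),
               2 * exp(-1), tolerance = 1e-12)
  expect_equal(expected_detected_fraction(1, dp, dt = dt,
                                          trap_dwell_mean_s = 1e6), 1,
               tolerance = 1e-6)
  # occupancy scales the fraction linearly
  expect_equal(expected_detected_fraction(0.5, dp, dt = dt,
                                          trap_dwell_mean_s = 0.338),
               0.5 * 0.912, tolerance = 1e-3)

  # detected mean duration: T + tau
  expect_equal(expected_detected_mean_duration(dp, 0.165, dt),
               5 * dt + 0.165)
  expect_equal(expected_detected_mean_duration(dp, 1e-9, dt), 5 * dt,
               tolerance = 1e-6)
  # matches the Monte-Carlo mean of exponential dwells truncated at T
  set.seed(10)
  x <- rexp(1e5, 1 / 0.165)
  expect_equal(mean(x[x >= Tthr]) , 5 * dt + 0.165, tolerance = 0.01)
})

test_that("occupancy calibration inverts the detected-fraction oracle", {
  dp <- trap_params()
  for (target in c(0.01, 0.081, 0.46)) {
    occ <- calibrate_occupancy(target, 0.338, dp)
    expect_equal(expected_detected_fraction(occ, dp, dt = 1 / 30,
                                            trap_dwell_mean_s = 0.338),
                 target, tolerance = 1e-12)
  }
  expect_equal(calibrate_occupancy(0, 0.338, dp), 0)
  expect_error(calibrate_occupancy(0.99, 0.05, dp), "infeasible")
})

test_that("the detector recovers hidden trapped frames with high recall and precision", {
  p <- sim_preset(d_free = 0.3, trap_dwell_mean_s = 0.4, occupancy = 0.3,
                  trap_conf_sd_nm = 10, sigma_axis_nm = 14,
                  n_cells = 4, trajectories_per_cell = 60)
  ts <- simulate_experiment(p, seed = 77)
  ts <- filter_min_length(ts, 10, quiet = TRUE)
  fit <- fit_trapping(ts, sigma_axis_nm = 14)
  # frame-level confusion restricted to dwells long enough to detect
  tp <- fp <- fn <- tn <- 0
  key <- paste(fit$events$cell_id, fit$events$trajectory_id)
  for (tr in ts$trajectories) {
    truth <- attr(tr, "trapped")
    det <- logical(n_frames(tr))
    ev <- fit$events[key == paste(tr$cell_id, tr$trajectory_id), ,
                     drop = FALSE]
    for (i in seq_len(nrow(ev)))
      det[(ev$start_frame[i]:ev$end_frame[i]) + 1L] <- TRUE
    # ground-truth dwells of >= 5 frames
    r <- rle(truth)
    long <- rep(r$values & r$lengths >= 5, r$lengths)
    tp <- tp + sum(det & long); fn <- fn + sum(!det & long)
    fp <- fp + sum(det & !truth); tn <- tn + sum(!det & !truth)
  }
  recall <- tp / (tp + fn)
  precision_free <- tn / (tn + fp)
  expect_gt(recall, 0.9)
  expect_gt(precision_free, 0.99)
})
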