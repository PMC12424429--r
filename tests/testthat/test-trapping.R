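test_that("a perfectly confined track yields one full-length event", {
  tr <- make_traj(rep(0.5, 10), rep(0.5, 10))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 10L)
  expect_equal(ev$duration_s, 10 / 30)
  expect_equal(ev$raw_sd_nm, 0)
})

test_that("a two-zone track yields the two events found by exhaustive enumeration", {
  set.seed(5)
  # frames 1-6 within 30 nm of the origin, frame 7 far away at (1, 0) um is
  # followed by frames 8-13 near (1, 0); frames 14-15 are far from both
  near0 <- matrix(runif(12, -0.02, 0.02), ncol = 2)
  near1 <- matrix(runif(12, -0.02, 0.02), ncol = 2)
  x <- c(near0[, 1], 1, 1 + near1[, 1], 3, 5)
  y <- c(near0[, 2], 0, near1[, 2], 3, 5)
  tr <- make_traj(x, y)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_frames, c(6L, 7L))
  # cross-check against the brute-force enumeration of qualifying windows:
  # each detected event must be a qualifying window, and the union of
  # detected frames must cover every frame that belongs to some window
  wins <- qualifying_windows(x, y)
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_frame[i] + 1; e <- ev$end_frame[i] + 1
    expect_true(any(vapply(wins, function(w) w[1] == s && w[2] == e ||
                             (w[1] <= s && w[2] >= e), logical(1))))
  }
  covered <- sort(unique(unlist(lapply(wins, function(w) w[1]:w[2]))))
  detected <- sort(unique(unlist(mapply(seq,
                                        ev$start_frame + 1, ev$end_frame + 1,
                                        SIMPLIFY = FALSE))))
  expect_equal(detected, covered)
})

test_that("zone size correction removes noise in quadrature", {
  # stationary emitter with noise sigma: raw^2 ~ 2 sigma^2, corrected ~ 0
  set.seed(21)
  sig <- 14
  xs <- replicate(400, {
    x <- rnorm(20, 0, sig / 1000); y <- rnorm(20, 0, sig / 1000)
    zone_size(x, y, sig)$raw_sd_nm^2
  })
  expect_equal(mean(xs), 2 * sig^2, tolerance = 0.05 * 2 * sig^2)

  # true per-axis scatter s plus noise: corrected recovers sqrt(2) s
  for (s in c(10, 20, 30)) {
    cors <- replicate(400, {
      x <- rnorm(25, 0, sqrt(s^2 + sig^2) / 1000)
      y <- rnorm(25, 0, sqrt(s^2 + sig^2) / 1000)
      zone_size(x, y, sig)$corrected_sd_nm
    })
    expect_equal(mean(cors), sqrt(2) * s, tolerance = 0.15 * sqrt(2) * s)
  }

  # reporting convention: corrected SD of 25.24 nm is a 637.1 pi nm^2 zone
  expect_equal(25.24^2, 637.1, tolerance = 1e-3)
  z <- zone_size(c(0, 0.01, -0.01, 0.02), c(0, -0.01, 0.01, 0.005), 0)
  expect_equal(z$zone_area_pi_nm2, z$corrected_sd_nm^2)
})

test_that("per-cell summaries follow the temporal-fraction and frequency definitions", {
  # one 20-frame trajectory with exactly one 5-frame event: fraction 25%
  set.seed(3)
  far <- seq(0, by = 0.4, length.out = 15)
  x <- c(far[1:10], rep(far[10], 5) + rnorm(5, 0, 1e-4), far[11:15] + 2)
  y <- c(far[1:10], rep(0, 5), far[11:15] + 2)
  y[1:10] <- far[1:10]
  tr <- make_traj(x, y)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 5L)
  ev$cell_id <- "cellA"
  cs <- summarize_cells(track_set(list(tr)), ev)
  expect_equal(cs$temporal_fraction, 100 * 5 / 20)
  expect_equal(cs$frequency, 1 / (20 / 30))

  # no events: zero fraction and frequency
  no_events <- cbind(cell_id = character(), sptrap:::.empty_events())
  cs0 <- summarize_cells(track_set(list(tr)), no_events)
  expect_equal(cs0$temporal_fraction, 0)
  expect_equal(cs0$frequency, 0)
})

test_that("detection is invariant under translation and rotation", {
  set.seed(77)
  p <- sim_preset(d_free = 0.3, trap_dwell_mean_s = 0.3, occupancy = 0.3,
                  n_cells = 1, trajectories_per_cell = 1, movie_frames = 120,
                  bleach_lifetime_s = Inf)
  tr <- simulate_trajectory(p)
  ev <- detect_events(tr, sigma_axis_nm = 14)
  th <- -1.1
  tr2 <- make_traj(cos(th) * tr$x - sin(th) * tr$y + 7,
                   sin(th) * tr$x + cos(th) * tr$y - 4)
  ev2 <- detect_events(tr2, sigma_axis_nm = 14)
  expect_equal(ev2$start_frame, ev$start_frame)
  expect_equal(ev2$end_frame, ev$end_frame)
  expect_equal(ev2$raw_sd_nm, ev$raw_sd_nm, tolerance = 1e-9)
})

test_that("re-running detection on a detected event's frames returns one spanning event", {
  set.seed(13)
  p <- sim_preset(d_free = 0.5, trap_dwell_mean_s = 0.4, occupancy = 0.4,
                  n_cells = 1, trajectories_per_cell = 1, movie_frames = 200,
                  bleach_lifetime_s = Inf)
  found <- 0
  for (s in 1:20) {
    set.seed(s)
    tr <- simulate_trajectory(p)
    ev <- detect_events(tr, sigma_axis_nm = 14)
    if (!nrow(ev)) next
    for (i in seq_len(nrow(ev))) {
      idx <- (ev$start_frame[i]:ev$end_frame[i]) + 1L
      if (length(idx) < 10) next   # detector requires >= 10-frame tracks
      sub <- make_traj(tr$x[idx], tr$y[idx])
      ev2 <- detect_events(sub, sigma_axis_nm = 14)
      expect_equal(nrow(ev2), 1L)
      expect_equal(ev2$n_frames, length(idx))
      found <- found + 1
    }
  }
  expect_gt(found, 3)
})

test_that("detected trapping time grows with radius and shrinks with min frames", {
  set.seed(55)
  p <- sim_preset(d_free = 0.3, trap_dwell_mean_s = 0.25, occupancy = 0.25,
                  n_cells = 1, trajectories_per_cell = 40)
  ts <- simulate_experiment(p, seed = 8)
  total_time <- function(radius, minf) {
    f <- fit_trapping(ts, trap_params(radius_nm = radius,
                                      min_event_frames = minf),
                      sigma_axis_nm = 14)
    sum(f$events$duration_s)
  }
  base <- total_time(50, 5)
  expect_gte(total_time(80, 5), base)
  expect_gte(total_time(50, 4), base)
  expect_lte(total_time(30, 5), base)
  expect_lte(total_time(50, 7), base)
})

test_that("free Brownian motion at mobile diffusivities is almost never called trapped", {
  p <- sim_preset(d_free = 0.5, occupancy = 0, trap_dwell_mean_s = 0.1,
                  n_cells = 4, trajectories_per_cell = 150)
  ts <- simulate_experiment(p, seed = 31)
  f <- fit_trapping(ts, sigma_axis_nm = 14)
  expect_lt(mean(f$cells$temporal_fraction), 1)
})

test_that("duration/size tables feed the rank correlation as expected", {
  # independent sizes and durations: |rho| small
  set.seed(66)
  n <- 4000
  tab <- data.frame(duration_s = rexp(n, 3), zone_area_pi_nm2 = rexp(n, 1 / 300))
  ct <- spearman_rho(tab$duration_s, tab$zone_area_pi_nm2)
  expect_lt(abs(ct$rho), 0.05)

  # coupling longer dwells to smaller zones: rho < 0 recovered
  dur <- rexp(n, 3)
  size <- 500 * exp(-dur) * exp(rnorm(n, 0, 0.3))
  ct2 <- spearman_rho(dur, size)
  expect_lt(ct2$rho, -0.5)

  # empty event set gives an empty table
  expect_equal(nrow(duration_size_table(sptrap:::.empty_events())), 0L)
})
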