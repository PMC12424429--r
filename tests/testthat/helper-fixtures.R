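# Fixture builders shared across tests. All randomness is seeded locally.

make_traj <- function(x, y, frame = seq_along(x) - 1L, dt = 1 / 30,
                      cell = "cellA", channel = "green", id = "t1",
                      intensity = rep(100, length(x))) {
  sptrap:::new_trajectory(cell, channel, id, frame, x, y, intensity, dt)
}

# pure Brownian track with optional static localization noise (um)
brownian_traj <- function(n, d, dt = 1 / 30, sigma_um = 0, ...) {
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * d * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * d * dt))))
  make_traj(x + rnorm(n, 0, sigma_um), y + rnorm(n, 0, sigma_um), dt = dt, ...)
}

# random spot table with gap-free trajectories, for I/O round trips
random_spot_table <- function(n_traj = 5, max_len = 12) {
  rows <- lapply(seq_len(n_traj), function(i) {
    len <- sample(2:max_len, 1)
    data.frame(cell_id = sample(c("c1", "c2"), 1), channel = "green",
               trajectory_id = paste0("tr", i),
               frame = seq(sample(0:5, 1), length.out = len),
               x_um = round(runif(len, 0, 20), 6),
               y_um = round(runif(len, 0, 20), 6),
               intensity = round(runif(len, 10, 1000), 6),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# independent brute-force MSD (naive double loop), the oracle for compute_msd
naive_msd <- function(x, y, n) {
  N <- length(x)
  acc <- 0
  for (j in 1:(N - n))
    acc <- acc + (x[j + n] - x[j])^2 + (y[j + n] - y[j])^2
  acc / (N - n)
}

# exhaustive enumeration of all windows qualifying as trapping events:
# every (start, end) with length >= min_f whose members all lie within
# radius of the window centroid
qualifying_windows <- function(x, y, radius_nm = 50, min_f = 5) {
  r2 <- (radius_nm / 1000)^2
  N <- length(x)
  out <- list()
  for (s in 1:(N - min_f + 1)) for (e in (s + min_f - 1):N) {
    cx <- mean(x[s:e]); cy <- mean(y[s:e])
    if (all((x[s:e] - cx)^2 + (y[s:e] - cy)^2 <= r2))
      out[[length(out) + 1]] <- c(s, e)
  }
  out
}

# brute-force Mann-Whitney U (count of pairs a_i > b_j, ties count 1/2)
brute_U <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
  u
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
brute_mw_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(ii) brute_U(pool[ii], pool[-ii]))
  u_obs <- brute_U(a, b)
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
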