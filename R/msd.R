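#' Overlapping-window mean-square displacement of one trajectory
#'
#' For a trajectory of N positions at fixed interval dt, the MSD at lag n is
#' the average of the squared n-step displacements over all overlapping
#' windows,
#' \deqn{MSD(n \delta t) = \frac{1}{N-n} \sum_{j=1}^{N-n}
#'   [x_{j+n}-x_j]^2 + [y_{j+n}-y_j]^2,}
#' i.e. every pair of positions n frames apart contributes once.
#'
#' @param traj An `sm_trajectory`.
#' @param n_max Largest lag (frames); must be `<= N - 1`. Default `N - 1`.
#' @return An object of class `msd_profile`: a `data.frame` with columns
#'   `lag` (frames), `delta_t` (s), `msd` (um^2) and `n_windows`.
#' @export
#' @examples
#' p <- sim_preset(d_free = 0.2, occupancy = 0, trap_dwell_mean_s = 0.1)
#' tr <- simulate_experiment(p, seed = 1)$trajectories[[1]]
#' compute_msd(tr, 7)
compute_msd <- function(traj, n_max = NULL) {
  stopifnot(inherits(traj, "sm_trajectory"))
  N <- n_frames(traj)
  if (is.null(n_max)) n_max <- N - 1L
  if (n_max >= N)
    stop("n_max must be at most N - 1 (got n_max = ", n_max,
         " for a trajectory of ", N, " frames)")
  stopifnot(n_max >= 1)
  x <- traj$x; y <- traj$y
  lags <- seq_len(n_max)
  msd <- vapply(lags, function(n) {
    dx <- x[(1L + n):N] - x[1L:(N - n)]
    dy <- y[(1L + n):N] - y[1L:(N - n)]
    mean(dx * dx + dy * dy)
  }, numeric(1L))
  structure(data.frame(lag = lags, delta_t = lags * traj$dt, msd = msd,
                       n_windows = N - lags),
            class = c("msd_profile", "data.frame"), dt = traj$dt)
}

#' @export
plot.msd_profile <- function(x, ...) {
  graphics::plot(x$delta_t, x$msd, xlab = expression(Delta * t ~ (s)),
                 ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

.d200_lags <- 5:7

#' Short-timescale diffusion coefficient D200ms
#'
#' Fits an ordinary least-squares line (with intercept) through the MSD
#' values at the 167, 200 and 233 ms lags (frames 5, 6 and 7 at video rate);
#' the slope divided by 4 is the two-dimensional diffusion coefficient on
#' the ~200 ms timescale. The intercept absorbs the lag-independent
#' localization-noise offset (approximately `4 sigma^2`), so static noise
#' biases the intercept, not the slope. Estimates from short noisy tracks
#' may be negative; they are retained (and later classified immobile) so
#' that percentile-based threshold calibration stays well defined.
#'
#' By default the MSD uses all overlapping windows of the full trajectory.
#' Set `first_frames = 10` to reproduce the literal 330-ms protocol that
#' uses only the first 10 frames of each trajectory.
#'
#' @param traj An `sm_trajectory` with at least 8 frames.
#' @param first_frames If non-`NULL`, truncate the trajectory to its first
#'   `first_frames` frames before computing the MSD.
#' @param lags Integer lags used for the fit (default 5:7).
#' @param warn_dt Warn when the frame interval differs from 1/30 s by more
#'   than 5% (the lag frames then no longer correspond to ~200 ms).
#' @return A list of class `diffusion_estimate` with elements `d200`
#'   (um^2/s), `intercept` (um^2), `n_frames` and `mobility` (`NA` until
#'   [classify_mobility()] is applied), or `NULL` when the trajectory is too
#'   short (such trajectories are excluded from D summaries).
#' @export
estimate_d200 <- function(traj, first_frames = NULL, lags = .d200_lags,
                          warn_dt = TRUE) {
  stopifnot(inherits(traj, "sm_trajectory"))
  if (warn_dt && abs(traj$dt - 1 / 30) / (1 / 30) > 0.05)
    warning("frame interval ", signif(traj$dt, 4), " s differs from 1/30 s ",
            "by more than 5%; lags ", paste(range(lags), collapse = "-"),
            " no longer probe the ~200 ms timescale")
  if (!is.null(first_frames)) {
    keep <- seq_len(min(first_frames, n_frames(traj)))
    traj$frame <- traj$frame[keep]; traj$x <- traj$x[keep]
    traj$y <- traj$y[keep]; traj$intensity <- traj$intensity[keep]
  }
  N <- n_frames(traj)
  if (N < max(lags) + 1L) return(NULL)
  prof <- compute_msd(traj, max(lags))
  tt <- prof$delta_t[lags]
  mm <- prof$msd[lags]
  fit <- stats::lsfit(tt, mm)
  structure(list(d200 = unname(fit$coefficients[2L]) / 4,
                 intercept = unname(fit$coefficients[1L]),
                 n_frames = N, mobility = NA_character_),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D200ms = %.4g um^2/s (intercept %.3g um^2, %d frames%s)\n",
              x$d200, x$intercept, x$n_frames,
              if (is.na(x$mobility)) "" else paste0(", ", x$mobility)))
  invisible(x)
}

#' Classify mobility from D200ms
#'
#' A trajectory is immobile when its D200ms lies strictly below the
#' threshold (default 0.009 um^2/s, the value calibrated as the 95th
#' percentile of immobilized reference molecules). Negative estimates fall
#' below any positive threshold and are therefore immobile.
#'
#' @param d200 Numeric vector of D200ms values, or a `diffusion_estimate`.
#' @param threshold Immobile threshold, um^2/s (> 0).
#' @return Character vector `"immobile"`/`"mobile"` (or the updated
#'   `diffusion_estimate`).
#' @export
classify_mobility <- function(d200, threshold = 0.009) {
  stopifnot(threshold > 0)
  if (inherits(d200, "diffusion_estimate")) {
    d200$mobility <- classify_mobility(d200$d200, threshold)
    return(d200)
  }
  ifelse(d200 < threshold, "immobile", "mobile")
}

#' Calibrate the immobile threshold from a reference population
#'
#' Returns the 95th percentile (linear-interpolation, type 7) of the D200ms
#' values of reference trajectories of immobilized molecules, so that by
#' construction 95% of the reference classifies immobile at the returned
#' threshold.
#'
#' @param reference A `track_set` of immobilized molecules, or a numeric
#'   vector of their D200ms values.
#' @param prob Percentile used (default 0.95).
#' @param ... Passed to [estimate_d200()] when `reference` is a track set.
#' @return Threshold in um^2/s.
#' @export
calibrate_immobile_threshold <- function(reference, prob = 0.95, ...) {
  d <- if (inherits(reference, "track_set")) {
    est <- lapply(reference$trajectories, estimate_d200, ...)
    vapply(Filter(Negate(is.null), est), `[[`, numeric(1L), "d200")
  } else as.numeric(reference)
  d <- d[is.finite(d)]
  if (length(d) < 2L)
    stop("need at least 2 reference trajectories with a D200ms estimate")
  if (length(d) < 20L)
    warning("fewer than 20 reference trajectories; the calibrated ",
            "threshold will be unstable")
  unname(stats::quantile(d, prob, type = 7))
}

#' Per-trajectory diffusion estimates for a track set
#'
#' Runs [estimate_d200()] on every trajectory and classifies mobility.
#' Trajectories too short for the 3-lag fit (fewer than 8 frames) are
#' dropped.
#'
#' @param ts A `track_set` (apply [filter_min_length()] first to reproduce
#'   the >= 10-frame analysis convention).
#' @param threshold Immobile threshold, um^2/s.
#' @param first_frames See [estimate_d200()].
#' @return Object of class `spt_diffusion`: a `data.frame` with columns
#'   `cell_id, channel, trajectory_id, n_frames, d200, intercept, mobility`,
#'   with the threshold stored as attribute `threshold`.
#' @export
fit_diffusion <- function(ts, threshold = 0.009, first_frames = NULL) {
  stopifnot(inherits(ts, "track_set"))
  rows <- list()
  warn_dt <- TRUE
  for (tr in ts$trajectories) {
    est <- estimate_d200(tr, first_frames = first_frames, warn_dt = warn_dt)
    warn_dt <- FALSE   # once per track set is enough
    if (is.null(est)) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = tr$cell_id, channel = tr$channel,
      trajectory_id = tr$trajectory_id, n_frames = est$n_frames,
      d200 = est$d200, intercept = est$intercept,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), channel = character(),
               trajectory_id = character(), n_frames = integer(),
               d200 = numeric(), intercept = numeric(),
               stringsAsFactors = FALSE)
  df$mobility <- classify_mobility(df$d200, threshold)
  structure(df, class = c("spt_diffusion", "data.frame"),
            threshold = threshold, dt = ts$dt)
}

#' @export
print.spt_diffusion <- function(x, ...) {
  cat(sprintf("D200ms estimates for %d trajectories (threshold %.4g um^2/s)\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x))
    cat(sprintf(" median D200ms %.4g um^2/s, immobile fraction %.1f%%\n",
                stats::median(x$d200),
                100 * mean(x$mobility == "immobile")))
  invisible(x)
}

#' Condition-level diffusion summary
#'
#' @param d An `spt_diffusion` table (from [fit_diffusion()]) or a
#'   `track_set` (which is fitted first).
#' @param threshold Immobile threshold, um^2/s, used when `d` is a track set.
#' @param breaks Number of log-spaced histogram bins.
#' @param ... Passed to [fit_diffusion()].
#' @return Object of class `diffusion_summary`: list with `n`, `median_d200`
#'   (um^2/s), `immobile_fraction` (percent of trajectories), and a
#'   log-spaced `histogram` (`breaks` in um^2/s, `counts`; non-positive
#'   estimates are counted in `n_nonpositive` and appear only in the
#'   immobile fraction).
#' @export
summarize_diffusion <- function(d, threshold = 0.009, breaks = 30L, ...) {
  if (inherits(d, "track_set")) d <- fit_diffusion(d, threshold, ...)
  stopifnot(inherits(d, "spt_diffusion"))
  if (!nrow(d)) stop("no diffusion estimates to summarize")
  pos <- d$d200[d$d200 > 0]
  hist <- if (length(pos) >= 2L && diff(range(pos)) > 0) {
    br <- 10 ^ seq(log10(min(pos)), log10(max(pos)), length.out = breaks + 1L)
    h <- graphics::hist(pos, breaks = br, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  } else NULL
  structure(list(n = nrow(d),
                 median_d200 = stats::median(d$d200),
                 immobile_fraction = 100 * mean(d$mobility == "immobile"),
                 threshold = attr(d, "threshold"),
                 n_nonpositive = sum(d$d200 <= 0),
                 histogram = hist),
            class = "diffusion_summary")
}

#' @export
print.diffusion_summary <- function(x, ...) {
  cat(sprintf(paste0("diffusion summary: n = %d trajectories\n",
                     " median D200ms   %.4g um^2/s\n",
                     " immobile        %.2f%% (threshold %.4g um^2/s)\n"),
              x$n, x$median_d200, x$immobile_fraction, x$threshold))
  invisible(x)
}

#' @export
plot.spt_diffusion <- function(x, ...) {
  pos <- x$d200[x$d200 > 0]
  if (!length(pos)) stop("no positive D200ms estimates to plot")
  graphics::hist(log10(pos), xlab = expression(log[10] ~ D["200ms"]),
                 main = "", ...)
  graphics::abline(v = log10(attr(x, "threshold")), lty = 2)
  invisible(x)
}
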