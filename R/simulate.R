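#' Two-state simulation preset
#'
#' Generative parameters for one experimental condition: a molecule
#' alternates between free Brownian diffusion (diffusivity `d_free`) and
#' trapped residency in a fixed zone (true positions scattered i.i.d. about
#' the trap center with per-axis SD `trap_conf_sd_nm`). State dwell times
#' are exponential with means `trap_dwell_mean_s` and `free_dwell_mean_s`;
#' the long-run trapped occupancy is `trap/(trap+free)`. Exactly one of
#' `occupancy` and `free_dwell_mean_s` must be given (the other is
#' derived). Localization noise (`sigma_axis_nm` per axis) is added to all
#' positions and trajectories are truncated by photobleaching (geometric
#' per-frame survival, mean `bleach_lifetime_s`) and the movie length.
#'
#' @param d_free Free-state diffusion coefficient, um^2/s.
#' @param trap_dwell_mean_s Mean trapped dwell, s.
#' @param occupancy Target fraction of time trapped, in `[0, 1]`.
#' @param free_dwell_mean_s Mean free dwell, s.
#' @param trap_conf_sd_nm Per-axis SD of true positions about the trap
#'   center, nm.
#' @param sigma_axis_nm Per-axis localization precision, nm.
#' @param dt Frame interval, s.
#' @param bleach_lifetime_s Mean photobleaching lifetime, s (`Inf` to
#'   disable).
#' @param movie_frames Maximum trajectory length (default 300, a 10-s movie
#'   at video rate).
#' @param n_cells,trajectories_per_cell Experiment layout for
#'   [simulate_experiment()].
#' @param channel Channel label given to simulated trajectories.
#' @param note Free-text provenance note.
#' @return Object of class `sim_preset`.
#' @export
sim_preset <- function(d_free, trap_dwell_mean_s, occupancy = NULL,
                       free_dwell_mean_s = NULL, trap_conf_sd_nm = 10,
                       sigma_axis_nm = 14, dt = 1 / 30,
                       bleach_lifetime_s = 10.4, movie_frames = 300L,
                       n_cells = 20L, trajectories_per_cell = 200L,
                       channel = "green", note = NULL) {
  stopifnot(d_free >= 0, trap_dwell_mean_s > 0, trap_conf_sd_nm >= 0,
            sigma_axis_nm >= 0, dt > 0, bleach_lifetime_s > 0,
            movie_frames >= 1, n_cells >= 1, trajectories_per_cell >= 1)
  if (is.null(occupancy) && is.null(free_dwell_mean_s))
    stop("give either 'occupancy' or 'free_dwell_mean_s'")
  if (!is.null(occupancy) && !is.null(free_dwell_mean_s)) {
    implied <- trap_dwell_mean_s / (trap_dwell_mean_s + free_dwell_mean_s)
    if (abs(implied - occupancy) > 1e-8)
      stop("'occupancy' (", occupancy, ") inconsistent with the dwell ",
           "means (implied ", signif(implied, 4), ")")
  }
  if (is.null(occupancy))
    occupancy <- trap_dwell_mean_s / (trap_dwell_mean_s + free_dwell_mean_s)
  stopifnot(occupancy >= 0, occupancy <= 1)
  if (is.null(free_dwell_mean_s))
    free_dwell_mean_s <- if (occupancy %in% c(0, 1)) Inf else
      trap_dwell_mean_s * (1 - occupancy) / occupancy
  structure(list(d_free = d_free, trap_conf_sd_nm = trap_conf_sd_nm,
                 trap_dwell_mean_s = trap_dwell_mean_s,
                 free_dwell_mean_s = free_dwell_mean_s,
                 occupancy = occupancy, sigma_axis_nm = sigma_axis_nm,
                 dt = dt, bleach_lifetime_s = bleach_lifetime_s,
                 movie_frames = as.integer(movie_frames),
                 n_cells = as.integer(n_cells),
                 trajectories_per_cell = as.integer(trajectories_per_cell),
                 channel = channel, note = note),
            class = "sim_preset")
}

#' @export
print.sim_preset <- function(x, ...) {
  cat(sprintf(paste0("simulation preset: D_free %.3g um^2/s, occupancy %.3f\n",
                     " trap dwell %.0f ms, confinement SD %.0f nm, noise %.1f nm\n",
                     " dt %.4f s, bleach %.3g s, movie %d frames\n"),
              x$d_free, x$occupancy, 1000 * x$trap_dwell_mean_s,
              x$trap_conf_sd_nm, x$sigma_axis_nm, x$dt,
              x$bleach_lifetime_s, x$movie_frames))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

## exponential dwell rounded to whole frames (0 = dwell shorter than half a
## frame, invisible at the frame clock); keeps the mean dwell unbiased so the
## hidden-state occupancy converges to the preset occupancy
.dwell_frames <- function(mean_frames) {
  if (!is.finite(mean_frames)) return(.Machine$integer.max)
  as.integer(round(stats::rexp(1L, 1 / mean_frames)))
}

## geometric frame count with mean 'mean_frames' (photobleaching survival)
.geom_frames <- function(mean_frames) {
  if (!is.finite(mean_frames)) return(.Machine$integer.max)
  q <- 1 - exp(-1 / mean_frames)
  1L + stats::rgeom(1L, q)
}

#' Simulate one two-state trajectory
#'
#' Draws the bleach-limited length, the alternating free/trapped state
#' sequence (exponential dwells realized as geometric frame counts, i.e.
#' switches at frame boundaries), the true positions, and the observed
#' positions with per-axis localization noise. Uses the current RNG state;
#' seed via `set.seed()` or use [simulate_experiment()] for reproducible
#' multi-cell layouts.
#'
#' @param p A [sim_preset()].
#' @param cell_id,trajectory_id Labels for the returned trajectory.
#' @param start Starting true position, um.
#' @return An `sm_trajectory` whose attribute `"trapped"` holds the hidden
#'   per-frame state (logical) for oracle tests.
#' @export
simulate_trajectory <- function(p, cell_id = "cell1", trajectory_id = "t1",
                                start = c(0, 0)) {
  stopifnot(inherits(p, "sim_preset"))
  L <- min(.geom_frames(p$bleach_lifetime_s / p$dt), p$movie_frames)
  trapped <- logical(L)
  # state runs: exponential dwells rounded to whole frames; dwells shorter
  # than half a frame round to zero visible frames but still displace the
  # molecule (free) or pause it (trapped) at the sub-frame level
  runs <- list()
  if (p$occupancy == 1) {
    runs[[1L]] <- list(state = TRUE, k = L, dwell_s = L * p$dt)
    trapped[] <- TRUE
  } else if (p$occupancy == 0) {
    runs[[1L]] <- list(state = FALSE, k = L, dwell_s = L * p$dt)
  } else {
    state <- stats::runif(1L) < p$occupancy    # TRUE = trapped
    total <- 0L
    while (total < L) {
      tau_s <- if (state) p$trap_dwell_mean_s else p$free_dwell_mean_s
      dwell_s <- stats::rexp(1L, 1 / tau_s)
      k <- min(as.integer(round(dwell_s / p$dt)), L - total)
      runs[[length(runs) + 1L]] <- list(state = state, k = k,
                                        dwell_s = dwell_s)
      if (k > 0L) {
        if (state) trapped[(total + 1L):(total + k)] <- TRUE
        total <- total + k
      }
      state <- !state
    }
  }
  x <- numeric(L); y <- numeric(L)
  pos <- start
  step_sd <- sqrt(2 * p$d_free * p$dt)
  conf_sd <- p$trap_conf_sd_nm / 1000
  i <- 1L
  # free time elapsed since the last emitted frame, carried into the next
  # trap entry so the trap center sits a diffusion step away from the last
  # observed free position (molecules walk into traps, they do not have one
  # under their last localization)
  pending_free_s <- 0
  for (r in runs) {
    if (r$state) {
      if (i > 1L && pending_free_s > 0) {
        pos <- pos + stats::rnorm(2L, 0, sqrt(2 * p$d_free * pending_free_s))
        pending_free_s <- 0
      }
      if (r$k > 0L) {
        j <- i + r$k - 1L
        x[i:j] <- pos[1L] + stats::rnorm(r$k, 0, conf_sd)
        y[i:j] <- pos[2L] + stats::rnorm(r$k, 0, conf_sd)
        i <- j + 1L
      }
      # the trap center stays fixed; diffusion resumes from it
    } else {
      if (r$k > 0L) {
        j <- i + r$k - 1L
        first_sd <- if (i == 1L) 0 else
          sqrt(2 * p$d_free * (pending_free_s + p$dt))
        x[i:j] <- pos[1L] + cumsum(c(stats::rnorm(1L, 0, first_sd),
                                     stats::rnorm(r$k - 1L, 0, step_sd)))
        y[i:j] <- pos[2L] + cumsum(c(stats::rnorm(1L, 0, first_sd),
                                     stats::rnorm(r$k - 1L, 0, step_sd)))
        pos <- c(x[j], y[j])
        pending_free_s <- p$dt
        i <- j + 1L
      } else pending_free_s <- pending_free_s + r$dwell_s
    }
    if (i > L) break
  }
  noise_sd <- p$sigma_axis_nm / 1000
  xo <- x + stats::rnorm(L, 0, noise_sd)
  yo <- y + stats::rnorm(L, 0, noise_sd)
  tr <- new_trajectory(cell_id, p$channel, trajectory_id, 0:(L - 1L),
                       xo, yo, stats::rnorm(L, 1000, 50), p$dt)
  attr(tr, "trapped") <- trapped
  attr(tr, "true_x") <- x
  attr(tr, "true_y") <- y
  tr
}

#' Simulate a multi-cell experiment
#'
#' Generates `n_cells x trajectories_per_cell` trajectories. Each cell uses
#' its own RNG substream seed drawn from the master seed, so cells are
#' independent and the whole track set is bit-reproducible from
#' `(preset, seed)`.
#'
#' @param p A [sim_preset()].
#' @param seed Master seed (integer).
#' @param condition Label stored on the track set (defaults to the preset
#'   note).
#' @return A [track_set()] whose trajectories carry hidden-state
#'   attributes; channel models are filled from the preset.
#' @export
simulate_experiment <- function(p, seed = 1L, condition = NULL) {
  stopifnot(inherits(p, "sim_preset"))
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, p$n_cells)
  trajectories <- vector("list", p$n_cells * p$trajectories_per_cell)
  idx <- 1L
  for (ci in seq_len(p$n_cells)) {
    set.seed(cell_seeds[ci])
    cid <- sprintf("cell%02d", ci)
    for (tj in seq_len(p$trajectories_per_cell)) {
      trajectories[[idx]] <- simulate_trajectory(
        p, cell_id = cid, trajectory_id = sprintf("c%02d_t%04d", ci, tj))
      idx <- idx + 1L
    }
  }
  cm <- stats::setNames(
    list(channel_model(max(p$sigma_axis_nm, 1e-6), p$bleach_lifetime_s)),
    p$channel)
  track_set(trajectories, dt = p$dt, channel_models = cm,
            condition = if (is.null(condition)) p$note %||% NA_character_
                        else condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dual-color pairing preset
#'
#' @param bound_fraction Fraction of channel-2 molecules whose true
#'   positions copy a channel-1 molecule, in `[0, 1]`.
#' @param registration_offset_nm Systematic inter-channel offset, nm.
#' @param sigma_ch1_nm,sigma_ch2_nm Per-channel per-axis localization
#'   precisions, nm.
#' @param n_molecules Molecules per channel.
#' @param roi_side_um Side of the square ROI over which molecules start,
#'   um.
#' @return Object of class `pair_preset`.
#' @export
pair_preset <- function(bound_fraction, registration_offset_nm = 0,
                        sigma_ch1_nm = 14, sigma_ch2_nm = 18.7,
                        n_molecules = 50L, roi_side_um = 10) {
  stopifnot(bound_fraction >= 0, bound_fraction <= 1, n_molecules >= 1,
            roi_side_um > 0, sigma_ch1_nm >= 0, sigma_ch2_nm >= 0)
  structure(list(bound_fraction = bound_fraction,
                 registration_offset_nm = registration_offset_nm,
                 sigma_ch1_nm = sigma_ch1_nm, sigma_ch2_nm = sigma_ch2_nm,
                 n_molecules = as.integer(n_molecules),
                 roi_side_um = roi_side_um),
            class = "pair_preset")
}

#' Simulate a two-channel (dual-color) track set
#'
#' Channel-1 molecules follow the base preset's dynamics from uniform
#' starting positions in a square ROI. A fraction `bound_fraction` of
#' channel-2 molecules shares the true position sequence of its channel-1
#' partner (plus any registration offset); the remainder move
#' independently. Channel noises are independent. Bleaching is disabled so
#' both channels span the full movie (frame-synchronous acquisition).
#'
#' @param pp A [pair_preset()].
#' @param base A [sim_preset()] defining the motion model.
#' @param seed Integer seed.
#' @return A [track_set()] with channels `"green"` (channel 1) and `"red"`
#'   (channel 2); bound partners share the molecule index in their ids
#'   (`m<i>_g` / `m<i>_r`).
#' @export
simulate_pair <- function(pp, base, seed = 1L) {
  stopifnot(inherits(pp, "pair_preset"), inherits(base, "sim_preset"))
  set.seed(seed)
  base$bleach_lifetime_s <- Inf
  n <- pp$n_molecules
  n_bound <- round(pp$bound_fraction * n)
  off <- pp$registration_offset_nm / 1000
  trajectories <- list()
  for (i in seq_len(n)) {
    start <- stats::runif(2L, 0, pp$roi_side_um)
    b1 <- base; b1$sigma_axis_nm <- 0; b1$channel <- "green"
    t1 <- simulate_trajectory(b1, "cell01", sprintf("m%03d_g", i), start)
    tx <- t1$x; ty <- t1$y        # true positions (no noise yet)
    L <- n_frames(t1)
    t1$x <- tx + stats::rnorm(L, 0, pp$sigma_ch1_nm / 1000)
    t1$y <- ty + stats::rnorm(L, 0, pp$sigma_ch1_nm / 1000)
    if (i <= n_bound) {
      t2 <- new_trajectory("cell01", "red", sprintf("m%03d_r", i),
                           t1$frame,
                           tx + off + stats::rnorm(L, 0, pp$sigma_ch2_nm / 1000),
                           ty + off + stats::rnorm(L, 0, pp$sigma_ch2_nm / 1000),
                           rep(1000, L), base$dt)
    } else {
      start2 <- stats::runif(2L, 0, pp$roi_side_um)
      b2 <- base; b2$sigma_axis_nm <- pp$sigma_ch2_nm; b2$channel <- "red"
      t2 <- simulate_trajectory(b2, "cell01", sprintf("m%03d_r", i), start2)
    }
    trajectories[[length(trajectories) + 1L]] <- t1
    trajectories[[length(trajectories) + 1L]] <- t2
  }
  track_set(trajectories, dt = base$dt,
            channel_models = list(
              green = channel_model(max(pp$sigma_ch1_nm, 1e-6), 1e6),
              red = channel_model(max(pp$sigma_ch2_nm, 1e-6), 1e6)))
}

#' Length-biased fraction of trapped time in detectable dwells
#'
#' For exponential trapped dwells with mean `tau`, the fraction of total
#' trapped time that lies in dwells lasting at least the detector threshold
#' time `T = min_event_frames * dt` is `e^{-T/tau} (1 + T/tau)` (a
#' length-biased tail probability). Multiplying by the occupancy gives the
#' expected detected temporal fraction of trapping, ignoring excursion
#' fragmentation and end truncation (an upper bound, accurate for
#' confinement SD <= 10 nm).
#'
#' @param p A [sim_preset()] (or a numeric occupancy).
#' @param dp [trap_params()].
#' @param dt Frame interval (taken from `p` when it is a preset).
#' @param trap_dwell_mean_s Trapped dwell mean (taken from `p` likewise).
#' @return Expected detected fraction of time, in `[0, 1]`.
#' @export
expected_detected_fraction <- function(p, dp = trap_params(), dt = NULL,
                                       trap_dwell_mean_s = NULL) {
  if (inherits(p, "sim_preset")) {
    occ <- p$occupancy; dt <- p$dt; tau <- p$trap_dwell_mean_s
  } else {
    occ <- p
    stopifnot(!is.null(dt), !is.null(trap_dwell_mean_s))
    tau <- trap_dwell_mean_s
  }
  Tthr <- dp$min_event_frames * dt
  occ * exp(-Tthr / tau) * (1 + Tthr / tau)
}

#' Expected mean duration of detected trapping events
#'
#' An exponential dwell (mean `tau`) conditioned on exceeding the threshold
#' time `T = min_event_frames * dt` has mean `T + tau` (memorylessness).
#'
#' @param dp [trap_params()].
#' @param trap_dwell_mean_s Trapped dwell mean `tau`, s.
#' @param dt Frame interval, s.
#' @return Expected detected mean event duration, s.
#' @export
expected_detected_mean_duration <- function(dp = trap_params(),
                                            trap_dwell_mean_s, dt = 1 / 30) {
  dp$min_event_frames * dt + trap_dwell_mean_s
}

#' Invert the detected-fraction oracle to a ground-truth occupancy
#'
#' Returns the occupancy at which [expected_detected_fraction()] equals
#' `target_detected_fraction`, used to build presets whose detector output
#' matches a given temporal fraction.
#'
#' @param target_detected_fraction Desired detected fraction of time, in
#'   `[0, 1)`.
#' @param trap_dwell_mean_s Trapped dwell mean, s.
#' @param dp [trap_params()].
#' @param dt Frame interval, s.
#' @return Occupancy in `[0, 1]`; errors when the target is infeasible
#'   (would require occupancy > 1).
#' @export
calibrate_occupancy <- function(target_detected_fraction, trap_dwell_mean_s,
                                dp = trap_params(), dt = 1 / 30) {
  stopifnot(target_detected_fraction >= 0)
  if (target_detected_fraction == 0) return(0)
  factor <- expected_detected_fraction(1, dp, dt = dt,
                                       trap_dwell_mean_s = trap_dwell_mean_s)
  occ <- target_detected_fraction / factor
  if (occ > 1)
    stop("target detected fraction ", target_detected_fraction,
         " is infeasible for dwell mean ", trap_dwell_mean_s,
         " s (length-bias factor ", signif(factor, 4), ")")
  occ
}

#' Built-in simulation presets
#'
#' Presets reverse-engineered from printed population summaries of
#' video-rate KRAS-pathway imaging, for validation only: free-state
#' diffusivity, exponential trapped dwell mean (detected mean duration
#' minus the 5-frame threshold time, or the printed 2-min value directly
#' for `wt_post2`), and occupancy calibrated so the expected detected
#' temporal fraction matches the printed value. `immobile_ref` generates
#' stationary emitters (pure localization noise) for threshold calibration.
#'
#' @param name Preset name; `NULL` lists all presets.
#' @return A `sim_preset`, or a named list of all of them.
#' @export
sim_presets <- function(name = NULL) {
  dp <- trap_params()
  mk <- function(d_free, tau, target_fraction, note)
    sim_preset(d_free = d_free, trap_dwell_mean_s = tau,
               occupancy = calibrate_occupancy(target_fraction, tau, dp),
               note = note)
  presets <- list(
    wt_pre = mk(0.53, 0.239 - 5 / 30, 0.032,
                "wild-type-like, before stimulation (D 0.53, fraction 3.2%, mean duration 239 ms)"),
    wt_post2 = sim_preset(d_free = 0.53, trap_dwell_mean_s = 0.338,
                          occupancy = calibrate_occupancy(0.081, 0.338, dp),
                          note = "wild-type-like, 2 min post-stimulation peak (fraction 8.1%, dwell 338 ms)"),
    sos1 = {
      p <- mk(0.1, 0.308 - 5 / 30, 0.46,
              "GEF-like slow diffuser (D 0.1, fraction 46%, mean duration 308 ms)")
      p
    },
    braf = mk(0.093, 0.328 - 5 / 30, 0.23,
              "effector-kinase-like (D 0.093, fraction 23%, mean duration 328 ms)"),
    immobile_ref = sim_preset(d_free = 0, trap_dwell_mean_s = 1,
                              occupancy = 1, trap_conf_sd_nm = 0,
                              sigma_axis_nm = 14,
                              note = "stationary emitters for immobile-threshold calibration"))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Hidden-state occupancy of a simulated track set
#'
#' @param ts Track set from [simulate_experiment()].
#' @return Fraction of frames whose ground-truth state is trapped.
#' @export
true_occupancy <- function(ts) {
  st <- lapply(ts$trajectories, attr, "trapped")
  if (any(vapply(st, is.null, logical(1L))))
    stop("track set has no hidden-state attributes (not simulated?)")
  mean(unlist(st))
}
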