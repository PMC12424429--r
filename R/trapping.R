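#' Transient-trapping detector parameters
#'
#' A transient trapping event is a residency of at least `min_event_frames`
#' consecutive frames within a zone of `radius_nm` around the event
#' centroid (50 nm radius = 100 nm diameter; 5 frames = 166.7 ms at video
#' rate). Only trajectories with at least `min_traj_frames` frames are
#' analyzed.
#'
#' @param radius_nm Detection radius, nm (> 0).
#' @param min_event_frames Minimum residency, frames (>= 2).
#' @param min_traj_frames Minimum analyzed trajectory length, frames.
#' @return Object of class `trap_params`.
#' @export
trap_params <- function(radius_nm = 50, min_event_frames = 5L,
                        min_traj_frames = 10L) {
  stopifnot(radius_nm > 0, min_event_frames >= 2,
            min_traj_frames >= min_event_frames)
  structure(list(radius_nm = radius_nm,
                 min_event_frames = as.integer(min_event_frames),
                 min_traj_frames = as.integer(min_traj_frames)),
            class = "trap_params")
}

#' @export
print.trap_params <- function(x, ...) {
  cat(sprintf("trapping detector: radius %g nm, >= %d frames, trajectories >= %d frames\n",
              x$radius_nm, x$min_event_frames, x$min_traj_frames))
  invisible(x)
}

#' Trapping-zone size with localization-precision correction
#'
#' The raw zone size is the radial SD of the event positions about their
#' centroid, `sqrt(sum(|r_i - r_centroid|^2) / (n - 1))`. Localization
#' noise with
#' per-axis SD `sigma_axis` inflates the squared radial spread by
#' `2 sigma_axis^2`, so the corrected size subtracts it in quadrature:
#' `corrected_sd = sqrt(max(raw_sd^2 - 2 sigma_axis^2, 0))`. Zone sizes are
#' conventionally reported as an area in multiples of pi,
#' `zone_area_pi = corrected_sd^2` (in nm^2, i.e. area = zone_area_pi * pi).
#'
#' @param x,y Event positions in um.
#' @param sigma_axis_nm Per-axis localization precision, nm.
#' @return List with `raw_sd_nm`, `corrected_sd_nm`, `zone_area_pi_nm2`.
#' @export
zone_size <- function(x, y, sigma_axis_nm) {
  stopifnot(length(x) == length(y), length(x) >= 2L, sigma_axis_nm >= 0)
  n <- length(x)
  # n - 1 in the denominator (SD convention): the spread is measured about
  # the sample centroid, and the unbiased normalization matters for the
  # short (5-15 frame) events this is applied to
  raw <- sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / (n - 1)) * 1000
  corr <- sqrt(max(raw^2 - 2 * sigma_axis_nm^2, 0))
  list(raw_sd_nm = raw, corrected_sd_nm = corr,
       zone_area_pi_nm2 = corr^2)
}

.empty_events <- function() {
  data.frame(start_frame = integer(), end_frame = integer(),
             n_frames = integer(), duration_s = numeric(),
             x_c_um = numeric(), y_c_um = numeric(),
             raw_sd_nm = numeric(), corrected_sd_nm = numeric(),
             zone_area_pi_nm2 = numeric(), stringsAsFactors = FALSE)
}

#' Detect transient trapping events in one trajectory
#'
#' Greedy two-pass scan. Pass 1 anchors a candidate window at frame i and
#' grows it frame by frame while every member stays within the detection
#' radius of the running centroid. Pass 2 verifies all members against the
#' final centroid, trimming trailing frames that violate it. Windows of at
#' least `min_event_frames` frames are accepted; scanning resumes at the
#' frame after an accepted event, so events never overlap (earliest-start
#' tie-breaking). A single excursion frame terminates an event; there is no
#' excursion tolerance.
#'
#' @param traj An `sm_trajectory` with at least `p$min_traj_frames` frames.
#' @param p [trap_params()].
#' @param sigma_axis_nm Per-axis localization precision used for the zone
#'   size correction (0 disables the correction).
#' @return `data.frame` of events (possibly empty): `start_frame`,
#'   `end_frame` (inclusive, in the trajectory's frame numbering),
#'   `n_frames`, `duration_s` (frame count times dt), centroid
#'   `x_c_um`/`y_c_um`, `raw_sd_nm`, `corrected_sd_nm`, `zone_area_pi_nm2`.
#' @export
detect_events <- function(traj, p = trap_params(), sigma_axis_nm = 0) {
  stopifnot(inherits(traj, "sm_trajectory"), inherits(p, "trap_params"))
  N <- n_frames(traj)
  if (N < p$min_traj_frames)
    stop("trajectory has ", N, " frames; detector requires >= ",
         p$min_traj_frames)
  x <- traj$x; y <- traj$y
  r2 <- (p$radius_nm / 1000)^2
  minE <- p$min_event_frames
  events <- list()
  i <- 1L
  while (i <= N - minE + 1L) {
    # pass 1: grow while all members lie within radius of the running centroid
    k <- i
    sx <- x[i]; sy <- y[i]
    while (k < N) {
      m <- k - i + 2L
      nsx <- sx + x[k + 1L]; nsy <- sy + y[k + 1L]
      cx <- nsx / m; cy <- nsy / m
      seg <- i:(k + 1L)
      if (all((x[seg] - cx)^2 + (y[seg] - cy)^2 <= r2)) {
        k <- k + 1L; sx <- nsx; sy <- nsy
      } else break
    }
    # pass 2: verify against the final centroid, trimming trailing violators
    j <- k
    ok <- FALSE
    while (j - i + 1L >= minE) {
      seg <- i:j
      cx <- mean(x[seg]); cy <- mean(y[seg])
      if (all((x[seg] - cx)^2 + (y[seg] - cy)^2 <= r2)) { ok <- TRUE; break }
      j <- j - 1L
    }
    if (ok) {
      seg <- i:j
      zs <- zone_size(x[seg], y[seg], sigma_axis_nm)
      events[[length(events) + 1L]] <- data.frame(
        start_frame = traj$frame[i], end_frame = traj$frame[j],
        n_frames = j - i + 1L, duration_s = (j - i + 1L) * traj$dt,
        x_c_um = cx, y_c_um = cy, raw_sd_nm = zs$raw_sd_nm,
        corrected_sd_nm = zs$corrected_sd_nm,
        zone_area_pi_nm2 = zs$zone_area_pi_nm2, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(events)) do.call(rbind, events) else .empty_events()
}

#' Detect trapping events across a track set
#'
#' Applies the `>= min_traj_frames` filter, runs [detect_events()] on every
#' trajectory (using each channel's localization precision from the track
#' set's channel models, if present), and attaches per-cell summaries.
#'
#' @param ts A `track_set`.
#' @param p [trap_params()].
#' @param sigma_axis_nm Fallback per-axis precision (nm) for channels
#'   without a channel model.
#' @return Object of class `spt_trapping`: list with `events` (data frame,
#'   one row per event, keyed by cell/channel/trajectory), `cells` (per-cell
#'   summary from [summarize_cells()]), `params`, and `dt`.
#' @export
fit_trapping <- function(ts, p = trap_params(), sigma_axis_nm = 0) {
  stopifnot(inherits(ts, "track_set"))
  ts <- filter_min_length(ts, p$min_traj_frames, quiet = TRUE)
  rows <- list()
  for (tr in ts$trajectories) {
    sig <- sigma_axis_nm
    if (!is.null(ts$channel_models) &&
        !is.null(ts$channel_models[[tr$channel]]))
      sig <- ts$channel_models[[tr$channel]]$sigma_axis_nm
    ev <- detect_events(tr, p, sig)
    if (nrow(ev)) {
      ev <- cbind(data.frame(cell_id = tr$cell_id, channel = tr$channel,
                             trajectory_id = tr$trajectory_id,
                             stringsAsFactors = FALSE), ev)
      rows[[length(rows) + 1L]] <- ev
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(cell_id = character(), channel = character(),
                     trajectory_id = character(), stringsAsFactors = FALSE),
          .empty_events())
  structure(list(events = events, cells = summarize_cells(ts, events),
                 params = p, dt = ts$dt),
            class = "spt_trapping")
}

#' Per-cell trapping statistics
#'
#' The temporal fraction is 100 times the ratio of total trapping time to
#' total trajectory duration of the cell; the frequency is the number of
#' events per second of total trajectory duration. Cells without events get
#' 0% and 0 events/s. Only trajectories in `ts` (already length-filtered)
#' enter the denominators.
#'
#' @param ts The filtered `track_set` the events were detected on.
#' @param events Event table from [fit_trapping()] or [detect_events()]
#'   (must carry a `cell_id` column).
#' @return `data.frame` with one row per cell: `cell_id`, `event_count`,
#'   `total_track_time_s`, `temporal_fraction` (percent), `frequency`
#'   (events/s).
#' @export
summarize_cells <- function(ts, events) {
  stopifnot(inherits(ts, "track_set"))
  cells <- vapply(ts$trajectories, `[[`, "", "cell_id")
  times <- vapply(ts$trajectories, traj_duration, numeric(1L))
  total <- tapply(times, cells, sum)
  if (any(total <= 0) || !length(total))
    stop("zero total tracked time; nothing to summarize")
  ids <- names(total)
  evc <- vapply(ids, function(id) sum(events$cell_id == id), numeric(1L))
  evt <- vapply(ids, function(id)
    sum(events$duration_s[events$cell_id == id]), numeric(1L))
  data.frame(cell_id = ids, event_count = as.integer(evc),
             total_track_time_s = as.numeric(total),
             temporal_fraction = 100 * evt / as.numeric(total),
             frequency = evc / as.numeric(total),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired duration/zone-size table of trapping events
#'
#' One row per event, used for duration histograms, zone-size distributions
#' and the Spearman rank correlation of size against duration.
#'
#' @param events Event table (from [fit_trapping()]`$events` or
#'   [detect_events()]).
#' @return `data.frame` with columns `duration_s` and `zone_area_pi_nm2`.
#' @export
duration_size_table <- function(events) {
  if (inherits(events, "spt_trapping")) events <- events$events
  data.frame(duration_s = events$duration_s,
             zone_area_pi_nm2 = events$zone_area_pi_nm2)
}

#' @export
print.spt_trapping <- function(x, ...) {
  cat(sprintf("transient trapping: %d events in %d cell(s)\n",
              nrow(x$events), nrow(x$cells)))
  print(x$params)
  if (nrow(x$cells))
    cat(sprintf(" mean per-cell temporal fraction %.2f%%, frequency %.3f events/s\n",
                mean(x$cells$temporal_fraction), mean(x$cells$frequency)))
  if (nrow(x$events))
    cat(sprintf(" mean event duration %.0f ms, mean zone area %.0f pi nm^2\n",
                1000 * mean(x$events$duration_s),
                mean(x$events$zone_area_pi_nm2)))
  invisible(x)
}

#' @export
summary.spt_trapping <- function(object, ...) {
  print(object)
  if (nrow(object$events) >= 3L) {
    ct <- spearman_rho(object$events$duration_s,
                       object$events$zone_area_pi_nm2)
    cat(sprintf(" Spearman rho (size vs duration) = %.3f\n", ct$rho))
  }
  invisible(object)
}

#' @export
plot.spt_trapping <- function(x, ...) {
  if (!nrow(x$events)) stop("no events to plot")
  graphics::plot(1000 * x$events$duration_s, x$events$zone_area_pi_nm2,
                 xlab = "trapping duration (ms)",
                 ylab = expression("zone area (" * pi ~ nm^2 * ")"), ...)
  invisible(x)
}
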