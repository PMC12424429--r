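#' Channel model: localization precision and photobleaching lifetime
#'
#' Describes one imaging channel. `sigma_axis_nm` is the per-axis standard
#' deviation of repeated position determinations of a stationary emitter
#' (localization precision); `bleach_lifetime_s` is the mean time to
#' single-step photobleaching. Typical video-rate values for a green
#' (tdStayGold-like) and a red (TMR-like) probe are 14.0 nm / 10.4 s and
#' 18.7 nm / 8.1 s respectively.
#'
#' @param sigma_axis_nm Per-axis localization precision, nm (> 0).
#' @param bleach_lifetime_s Mean photobleaching lifetime, s (> 0; `Inf`
#'   disables bleaching in simulations).
#' @return An object of class `channel_model`.
#' @export
#' @examples
#' channel_model(14.0, 10.4)
channel_model <- function(sigma_axis_nm, bleach_lifetime_s) {
  stopifnot(is.numeric(sigma_axis_nm), length(sigma_axis_nm) == 1L,
            sigma_axis_nm > 0,
            is.numeric(bleach_lifetime_s), length(bleach_lifetime_s) == 1L,
            bleach_lifetime_s > 0)
  structure(list(sigma_axis_nm = sigma_axis_nm,
                 bleach_lifetime_s = bleach_lifetime_s),
            class = "channel_model")
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("channel model: sigma_axis %.1f nm, bleach lifetime %.1f s\n",
              x$sigma_axis_nm, x$bleach_lifetime_s))
  invisible(x)
}

#' Default channel models for a green/red dual-color setup
#'
#' @return Named list of [channel_model()] objects for channels `"green"`
#'   (14.0 nm, 10.4 s) and `"red"` (18.7 nm, 8.1 s).
#' @export
default_channel_models <- function() {
  list(green = channel_model(14.0, 10.4),
       red   = channel_model(18.7, 8.1))
}

## internal trajectory constructor; x, y in um, frame 0-based consecutive
new_trajectory <- function(cell_id, channel, trajectory_id, frame, x, y,
                           intensity, dt) {
  structure(list(cell_id = as.character(cell_id),
                 channel = as.character(channel),
                 trajectory_id = as.character(trajectory_id),
                 frame = as.integer(frame),
                 x = as.numeric(x), y = as.numeric(y),
                 intensity = as.numeric(intensity),
                 dt = dt),
            class = "sm_trajectory")
}

#' Number of frames of a trajectory
#' @param traj An `sm_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frame)

#' Tracked duration of a trajectory in seconds
#'
#' The convention used throughout is frame count times the frame interval,
#' so a 5-frame residency at dt = 1/30 s lasts 166.7 ms.
#' @param traj An `sm_trajectory`.
#' @return Duration in seconds.
#' @export
traj_duration <- function(traj) n_frames(traj) * traj$dt

#' @export
print.sm_trajectory <- function(x, ...) {
  cat(sprintf("trajectory %s (cell %s, channel %s): %d frames [%d..%d], dt %.4f s\n",
              x$trajectory_id, x$cell_id, x$channel, n_frames(x),
              x$frame[1L], x$frame[n_frames(x)], x$dt))
  invisible(x)
}

#' Construct a track set
#'
#' A `track_set` groups trajectories that share one frame interval, together
#' with per-channel imaging models and optional condition/time-point labels.
#'
#' @param trajectories List of `sm_trajectory` objects.
#' @param dt Frame interval in seconds shared by all trajectories.
#' @param channel_models Named list of [channel_model()] objects keyed by
#'   channel name (may be `NULL`).
#' @param condition,time_point Optional text labels.
#' @return An object of class `track_set`.
#' @export
track_set <- function(trajectories, dt = 1 / 30, channel_models = NULL,
                      condition = NA_character_, time_point = NA_character_) {
  stopifnot(is.list(trajectories), is.numeric(dt), dt > 0)
  for (tr in trajectories) {
    if (!inherits(tr, "sm_trajectory"))
      stop("all elements of 'trajectories' must be sm_trajectory objects")
    if (!isTRUE(all.equal(tr$dt, dt)))
      stop("all trajectories must share the track set frame interval 'dt'")
  }
  structure(list(trajectories = trajectories, dt = dt,
                 channel_models = channel_models,
                 condition = condition, time_point = time_point),
            class = "track_set")
}

#' @export
length.track_set <- function(x) length(x$trajectories)

#' @export
print.track_set <- function(x, ...) {
  n <- length(x$trajectories)
  cells <- unique(vapply(x$trajectories, `[[`, "", "cell_id"))
  chans <- unique(vapply(x$trajectories, `[[`, "", "channel"))
  cat(sprintf("track set: %d trajectories, %d cell(s), channel(s) %s, dt %.4f s\n",
              n, length(cells), paste(chans, collapse = "/"), x$dt))
  if (!is.na(x$condition)) cat(" condition:", x$condition, "\n")
  invisible(x)
}

#' @export
summary.track_set <- function(object, ...) {
  lens <- vapply(object$trajectories, n_frames, 1L)
  cat(sprintf("track set: %d trajectories, dt %.4f s\n",
              length(lens), object$dt))
  if (length(lens)) {
    cat(sprintf(" frames per trajectory: min %d, median %g, max %d\n",
                min(lens), stats::median(lens), max(lens)))
    cat(sprintf(" total tracked time: %.1f s\n", sum(lens) * object$dt))
  }
  invisible(object)
}

.spot_columns <- c("cell_id", "channel", "trajectory_id", "frame",
                   "x_um", "y_um", "intensity")

#' Convert a track set to a spot table
#'
#' @param x A `track_set`.
#' @param ... Unused.
#' @return `data.frame` with one localization per row and columns
#'   `cell_id, channel, trajectory_id, frame, x_um, y_um, intensity`.
#' @export
as.data.frame.track_set <- function(x, ...) {
  if (!length(x$trajectories))
    return(stats::setNames(
      data.frame(character(), character(), character(), integer(),
                 numeric(), numeric(), numeric(),
                 stringsAsFactors = FALSE), .spot_columns))
  parts <- lapply(x$trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, channel = tr$channel,
               trajectory_id = tr$trajectory_id, frame = tr$frame,
               x_um = tr$x, y_um = tr$y, intensity = tr$intensity,
               stringsAsFactors = FALSE))
  do.call(rbind, parts)
}

## group a validated spot table into trajectories, splitting at frame gaps
.spots_to_trajectories <- function(df, dt) {
  key <- paste(df$cell_id, df$channel, df$trajectory_id, sep = "\r")
  out <- list()
  for (grp in split(df, key)) {
    grp <- grp[order(grp$frame), , drop = FALSE]
    if (anyDuplicated(grp$frame))
      stop(sprintf("duplicate frame index for trajectory '%s' (cell '%s')",
                   grp$trajectory_id[1L], grp$cell_id[1L]))
    piece <- cumsum(c(1L, diff(grp$frame) > 1L))
    npiece <- piece[length(piece)]
    for (k in seq_len(npiece)) {
      sub <- grp[piece == k, , drop = FALSE]
      id <- if (npiece == 1L) sub$trajectory_id[1L] else
        paste0(sub$trajectory_id[1L], "_s", k)
      out[[length(out) + 1L]] <- new_trajectory(
        sub$cell_id[1L], sub$channel[1L], id, sub$frame,
        sub$x_um, sub$y_um, sub$intensity, dt)
    }
  }
  out
}

#' Read a trajectory CSV into a track set
#'
#' Reads a tidy spot table (one localization per row, columns
#' `cell_id, channel, trajectory_id, frame, x_um, y_um, intensity`; header
#' required, '.' decimal separator) as produced by any SPT tracker or by
#' [write_tracks()]. Rows are grouped into trajectories ordered by frame;
#' a trajectory containing frame gaps is split at every gap into separate
#' trajectories whose ids get `_s1`, `_s2`, ... suffixes, because the
#' downstream detectors assume strictly consecutive frames.
#'
#' @param path CSV file path.
#' @param dt Frame interval in seconds (default 1/30 s, i.e. video rate).
#' @param channel_models Optional named list of [channel_model()]s.
#' @param condition,time_point Optional labels stored on the track set.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, dt = 1 / 30, channel_models = NULL,
                        condition = NA_character_,
                        time_point = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.spot_columns, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    stop("non-finite coordinate in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "")
  if (any(df$frame < 0) || any(df$frame != round(df$frame)))
    stop("'frame' must contain non-negative integers")
  if (any(!is.finite(df$intensity) | df$intensity < 0))
    stop("'intensity' must be finite and >= 0")
  track_set(.spots_to_trajectories(df, dt), dt = dt,
            channel_models = channel_models,
            condition = condition, time_point = time_point)
}

#' Write a track set to a trajectory CSV
#'
#' Inverse of [read_tracks()] for gap-free track sets: the written file
#' reproduces the spot table up to row order. Coordinates are written with
#' full precision (lossless well beyond 6 decimal places).
#'
#' @param ts A `track_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Drop trajectories shorter than a minimum frame count
#'
#' Quantitative analysis of trapping and diffusion is restricted to
#' trajectories with at least `min_frames` frames (default 10, inclusive).
#' The number of removed trajectories is reported via [message()].
#'
#' @param ts A `track_set`.
#' @param min_frames Minimum retained length, frames (>= 2).
#' @param quiet Suppress the removal message.
#' @return Filtered `track_set`. Idempotent.
#' @export
filter_min_length <- function(ts, min_frames = 10L, quiet = FALSE) {
  stopifnot(inherits(ts, "track_set"), min_frames >= 2)
  keep <- vapply(ts$trajectories, n_frames, 1L) >= min_frames
  if (!quiet && any(!keep))
    message(sum(!keep), " trajectory(ies) shorter than ", min_frames,
            " frames removed")
  ts$trajectories <- ts$trajectories[keep]
  ts
}

#' Extract the spots of one channel as a per-frame table
#'
#' @param ts A `track_set`.
#' @param channel Channel name.
#' @return `data.frame` with columns `frame, x_um, y_um, trajectory_id`.
#' @export
channel_spots <- function(ts, channel) {
  df <- as.data.frame(ts)
  df <- df[df$channel == channel, c("frame", "x_um", "y_um", "trajectory_id")]
  rownames(df) <- NULL
  df
}

#' Read/write a flat key-value configuration file
#'
#' Configurations (frame interval, channel precisions, detector parameters,
#' simulation presets) are stored as flat YAML mappings.
#'
#' @param path File path.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Named list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @export
plot.track_set <- function(x, max_trajectories = 50L, ...) {
  trs <- x$trajectories[seq_len(min(length(x$trajectories), max_trajectories))]
  if (!length(trs)) stop("empty track set")
  xs <- unlist(lapply(trs, `[[`, "x"))
  ys <- unlist(lapply(trs, `[[`, "y"))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                 xlab = expression(x ~ (mu * m)),
                 ylab = expression(y ~ (mu * m)), ...)
  cols <- grDevices::hcl.colors(length(trs), "Dark 3")
  for (i in seq_along(trs))
    graphics::lines(trs[[i]]$x, trs[[i]]$y, col = cols[i])
  invisible(x)
}
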