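#' Standard error of the mean
#' @param x Numeric vector.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

## per-cell background-subtracted intensity sum over qualifying trajectories
.cell_intensity_sums <- function(ts, background, min_frames, inclusive) {
  qual <- vapply(ts$trajectories, function(tr) {
    n <- n_frames(tr)
    if (inclusive) n >= min_frames else n > min_frames
  }, logical(1L))
  trs <- ts$trajectories[qual]
  cells <- vapply(trs, `[[`, "", "cell_id")
  sums <- vapply(trs, function(tr) sum(tr$intensity - background),
                 numeric(1L))
  tapply(sums, cells, sum)
}

#' Membrane-recruitment time course from spot intensities
#'
#' Molecules persisting on the membrane for at least `min_frames` frames
#' are counted as recruited; for each cell and time point the
#' background-subtracted fluorescence intensities of all their spots are
#' summed, and the per-cell ratio relative to the reference time point
#' (canonically 1 min after stimulation) is formed. The time course reports
#' the mean ratio +/- SEM across cells.
#'
#' @param tracksets Named list mapping time-point label to `track_set`
#'   (cells matched across time points by `cell_id`).
#' @param reference Name of the reference time point (must be present).
#' @param background Mean background intensity per spot (a.u.), subtracted
#'   before summation.
#' @param min_frames Persistence threshold in frames (default 10).
#' @param inclusive Use `>= min_frames` (default, consistent with the
#'   trajectory-length convention elsewhere); `FALSE` uses the strict
#'   `> min_frames` reading.
#' @return Object of class `recruitment_timecourse`: a `data.frame` with
#'   columns `time`, `mean_ratio`, `sem`, `n_cells`, with the per-cell
#'   ratios in attribute `cell_ratios`.
#' @export
recruitment_timecourse <- function(tracksets, reference,
                                   background = 0, min_frames = 10L,
                                   inclusive = TRUE) {
  stopifnot(is.list(tracksets), length(tracksets) >= 1L,
            !is.null(names(tracksets)))
  if (!reference %in% names(tracksets))
    stop("reference time point '", reference, "' is missing")
  sums <- lapply(tracksets, .cell_intensity_sums, background = background,
                 min_frames = min_frames, inclusive = inclusive)
  ref <- sums[[reference]]
  if (!length(ref) || any(ref <= 0))
    stop("reference time point has no positive per-cell intensity sums")
  rows <- list(); ratios <- list()
  for (tp in names(tracksets)) {
    s <- sums[[tp]]
    cells <- intersect(names(s), names(ref))
    if (!length(cells))
      stop("no cells shared with the reference at time point '", tp, "'")
    r <- as.numeric(s[cells]) / as.numeric(ref[cells])
    ratios[[tp]] <- stats::setNames(r, cells)
    rows[[tp]] <- data.frame(time = tp, mean_ratio = mean(r),
                             sem = if (length(r) > 1L) sem(r) else NA_real_,
                             n_cells = length(r), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("recruitment_timecourse", "data.frame"),
            cell_ratios = ratios, reference = reference)
}

#' @export
print.recruitment_timecourse <- function(x, ...) {
  cat("recruitment time course (reference:", attr(x, "reference"), ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Normalized membrane spot density
#'
#' Spot counts normalized to both the total expression level of the probe
#' (whole-cell fluorescence intensity) and the observation area:
#' `density = count / (whole_cell_intensity * area)`.
#'
#' @param count Number of membrane-recruited spots (>= 0).
#' @param whole_cell_intensity Whole-cell fluorescence intensity, a.u. (> 0).
#' @param area_um2 Observation area, um^2 (> 0).
#' @return `data.frame` row with the inputs and `normalized_density`
#'   (spots per a.u. per um^2). Vectorized over its arguments.
#' @export
normalized_spot_density <- function(count, whole_cell_intensity, area_um2) {
  if (any(whole_cell_intensity <= 0) || any(area_um2 <= 0))
    stop("whole_cell_intensity and area_um2 must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  data.frame(count = count, whole_cell_intensity = whole_cell_intensity,
             area_um2 = area_um2,
             normalized_density = count / (whole_cell_intensity * area_um2))
}
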