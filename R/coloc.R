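#' Inter-channel pair-distance density distribution
#'
#' For every frame, all pairwise distances between molecules of the two
#' channels inside the ROI are measured and binned into annuli (default
#' 0-500 nm in 50-nm bins). Per-annulus counts are divided by the annulus
#' area `pi (r2^2 - r1^2)` and accumulated over frames, yielding a
#' distance-based pair density (pairs per nm^2). Under complete spatial
#' randomness the density is flat, so ratios of bins form a natural
#' colocalization measure. No edge correction is applied; the ROI must be
#' large relative to the largest bin edge (a warning is raised below a
#' 10-um-diameter equivalent area).
#'
#' @param spots_ch1,spots_ch2 Per-frame spot tables (`data.frame` with
#'   columns `frame`, `x_um`, `y_um`), e.g. from [channel_spots()].
#' @param roi_area_um2 ROI area in um^2 (> 0).
#' @param edges_nm Strictly increasing annulus edges in nm.
#' @return Object of class `pair_density`: list with `edges_nm`, `counts`
#'   (pairs per annulus, summed over frames), `density` (pairs/nm^2),
#'   `roi_area_um2`, `n_frames` (frames with spots in both channels) and
#'   `n_pairs`.
#' @export
pair_distance_density <- function(spots_ch1, spots_ch2, roi_area_um2,
                                  edges_nm = seq(0, 500, by = 50)) {
  stopifnot(roi_area_um2 > 0, length(edges_nm) >= 2L,
            all(diff(edges_nm) > 0))
  if (roi_area_um2 < pi * 5^2)
    warning("ROI area ", signif(roi_area_um2, 3), " um^2 is below a ",
            "10-um-diameter ROI; annulus densities near ",
            max(edges_nm), " nm will suffer edge effects")
  nb <- length(edges_nm) - 1L
  counts <- numeric(nb)
  n_frames <- 0L
  if (!nrow(spots_ch1) || !nrow(spots_ch2)) {
    warning("a channel has no spots; returning an empty density")
  } else {
    frames <- intersect(unique(spots_ch1$frame), unique(spots_ch2$frame))
    s1 <- split(spots_ch1, spots_ch1$frame)
    s2 <- split(spots_ch2, spots_ch2$frame)
    for (f in as.character(frames)) {
      a <- s1[[f]]; b <- s2[[f]]
      dx <- outer(a$x_um, b$x_um, "-")
      dy <- outer(a$y_um, b$y_um, "-")
      d_nm <- sqrt(dx * dx + dy * dy) * 1000
      h <- graphics::hist(d_nm[d_nm >= edges_nm[1L] & d_nm < edges_nm[nb + 1L]],
                          breaks = edges_nm, plot = FALSE, right = FALSE)
      counts <- counts + h$counts
      n_frames <- n_frames + 1L
    }
  }
  areas <- pi * (edges_nm[-1L]^2 - edges_nm[-(nb + 1L)]^2)
  structure(list(edges_nm = edges_nm, counts = counts,
                 density = counts / areas, roi_area_um2 = roi_area_um2,
                 n_frames = n_frames, n_pairs = sum(counts)),
            class = "pair_density")
}

#' @export
print.pair_density <- function(x, ...) {
  cat(sprintf("pair-distance density: %d pairs over %d frames, ROI %.1f um^2\n",
              x$n_pairs, x$n_frames, x$roi_area_um2))
  invisible(x)
}

#' @export
plot.pair_density <- function(x, ...) {
  mid <- (x$edges_nm[-1L] + x$edges_nm[-length(x$edges_nm)]) / 2
  graphics::plot(mid, x$density, type = "s",
                 xlab = "pair distance (nm)",
                 ylab = expression("pair density (" * nm^-2 * ")"), ...)
  invisible(x)
}

#' Colocalization index from a pair-distance density
#'
#' The ratio of molecular pairs within 0-50 nm to those within 400-500 nm.
#' By default each count is normalized by its annulus area before the ratio,
#' which makes the index 1 under spatial independence regardless of the
#' annulus geometry; `normalize = FALSE` gives the literal raw-count ratio.
#'
#' @param pd A `pair_density`.
#' @param near_nm,far_nm Distance windows `(lo, hi)` in nm; both must align
#'   with bin edges.
#' @param normalize Divide counts by annulus area before the ratio.
#' @return Object of class `coloc_index`: list with `value`, `n_pairs_near`,
#'   `n_pairs_far`, `normalized`, and `undefined` (`TRUE` with `value = NA`
#'   when the far window holds no pairs).
#' @export
coloc_index <- function(pd, near_nm = c(0, 50), far_nm = c(400, 500),
                        normalize = TRUE) {
  stopifnot(inherits(pd, "pair_density"))
  pick <- function(win) {
    lo <- match(win[1L], pd$edges_nm)
    hi <- match(win[2L], pd$edges_nm)
    if (is.na(lo) || is.na(hi) || hi <= lo)
      stop("window [", win[1L], ",", win[2L],
           ") nm does not align with the density bin edges")
    idx <- lo:(hi - 1L)
    list(count = sum(pd$counts[idx]),
         area = pi * (win[2L]^2 - win[1L]^2))
  }
  near <- pick(near_nm); far <- pick(far_nm)
  undefined <- far$count == 0
  value <- if (undefined) NA_real_ else if (normalize)
    (near$count / near$area) / (far$count / far$area)
  else near$count / far$count
  structure(list(value = value, n_pairs_near = near$count,
                 n_pairs_far = far$count, normalized = normalize,
                 undefined = undefined),
            class = "coloc_index")
}

#' @export
print.coloc_index <- function(x, ...) {
  if (x$undefined)
    cat("colocalization index: undefined (no pairs in the far window)\n")
  else
    cat(sprintf("colocalization index: %.3f (%d near / %d far pairs%s)\n",
                x$value, x$n_pairs_near, x$n_pairs_far,
                if (x$normalized) ", area-normalized" else ", raw counts"))
  invisible(x)
}

#' Frame-wise colocalization events between two trajectories
#'
#' Two simultaneously imaged molecules are colocalized in a frame when
#' their inter-channel distance is below `threshold_nm` (default 240 nm,
#' the separation at which truly associated molecules are scored together
#' in ~99% of frames given typical channel localization errors). Events are
#' maximal runs of consecutive common frames below the threshold.
#'
#' @param traj_ch1,traj_ch2 `sm_trajectory` objects sharing frame indexing.
#' @param threshold_nm Colocalization distance threshold, nm.
#' @return `data.frame` (possibly empty) with one row per event:
#'   `start_frame`, `end_frame`, `n_frames`, `duration_s`, `mean_dist_nm`.
#' @export
detect_coloc_events <- function(traj_ch1, traj_ch2, threshold_nm = 240) {
  stopifnot(inherits(traj_ch1, "sm_trajectory"),
            inherits(traj_ch2, "sm_trajectory"), threshold_nm > 0)
  common <- intersect(traj_ch1$frame, traj_ch2$frame)
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      n_frames = integer(), duration_s = numeric(),
                      mean_dist_nm = numeric())
  if (!length(common)) return(empty)
  common <- sort(common)
  i1 <- match(common, traj_ch1$frame)
  i2 <- match(common, traj_ch2$frame)
  d_nm <- sqrt((traj_ch1$x[i1] - traj_ch2$x[i2])^2 +
               (traj_ch1$y[i1] - traj_ch2$y[i2])^2) * 1000
  near <- d_nm < threshold_nm
  if (!any(near)) return(empty)
  # split candidate frames into runs that are consecutive in frame number
  idx <- which(near)
  run <- cumsum(c(1L, diff(common[idx]) > 1L | diff(idx) > 1L))
  rows <- lapply(split(idx, run), function(ii)
    data.frame(start_frame = common[ii[1L]],
               end_frame = common[ii[length(ii)]],
               n_frames = length(ii),
               duration_s = length(ii) * traj_ch1$dt,
               mean_dist_nm = mean(d_nm[ii])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
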