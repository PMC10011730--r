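#' Tracked patch trajectory
#'
#' Per-frame centroid positions and intensities of one tracked patch.
#' Frames are 0-based and must be strictly increasing.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `intensity`.
#' @param id Patch identifier.
#' @param frame_interval Seconds per frame.
#' @return An object of class `patch_trajectory` (list with `detections`,
#'   `id`, `frame_interval`).
#' @export
patch_trajectory <- function(detections, id = 1L, frame_interval = 1) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y", "intensity") %in% names(detections)),
            nrow(detections) >= 1, .is_num1(frame_interval),
            frame_interval > 0)
  if (is.unsorted(detections$frame, strictly = TRUE))
    .stopf("trajectory frames must be strictly increasing")
  rownames(detections) <- NULL
  structure(list(detections = detections, id = id,
                 frame_interval = frame_interval),
            class = "patch_trajectory")
}

#' @export
print.patch_trajectory <- function(x, ...) {
  d <- x$detections
  cat(sprintf("<patch_trajectory> id %s: %d detections, frames %d..%d @ %g s\n",
              x$id, nrow(d), min(d$frame), max(d$frame), x$frame_interval))
  invisible(x)
}

#' Patch lifetime from a trajectory
#'
#' Defined as `(last_frame - first_frame + 1) * frame_interval`, i.e. the
#' time span over which the patch was detected, counting both end frames.
#'
#' @param trajectory A [patch_trajectory()].
#' @return Lifetime in seconds.
#' @export
#' @examples
#' tr <- patch_trajectory(data.frame(frame = 0:19, x = 0, y = 0,
#'                                   intensity = 1))
#' lifetime(tr)  # 20
lifetime <- function(trajectory) {
  stopifnot(inherits(trajectory, "patch_trajectory"))
  f <- trajectory$detections$frame
  (max(f) - min(f) + 1) * trajectory$frame_interval
}

#' Per-frame centroid displacement
#'
#' Euclidean distance of the centroid from a reference point, per frame,
#' in micrometers. The reference is either the first detected position or
#' the mean position over the first `pre_frames` detections
#' ("pre-movement mean").
#'
#' @param trajectory A [patch_trajectory()].
#' @param pixel_size Micrometers per pixel (use 1 if positions are already
#'   in micrometers).
#' @param reference `"first-frame"` or `"pre-movement-mean"`.
#' @param pre_frames Number of initial detections averaged for the
#'   pre-movement reference.
#' @return Numeric vector of displacements, one per detection.
#' @export
centroid_displacement <- function(trajectory, pixel_size = 1,
                                  reference = c("first-frame",
                                                "pre-movement-mean"),
                                  pre_frames = 3) {
  stopifnot(inherits(trajectory, "patch_trajectory"))
  reference <- match.arg(reference)
  d <- trajectory$detections
  if (reference == "first-frame") {
    rx <- d$x[1]; ry <- d$y[1]
  } else {
    n <- min(pre_frames, nrow(d))
    rx <- mean(d$x[seq_len(n)]); ry <- mean(d$y[seq_len(n)])
  }
  sqrt((d$x - rx)^2 + (d$y - ry)^2) * pixel_size
}

#' Assembly onset time of a single trajectory
#'
#' Estimates when a patch started assembling from its own intensity series:
#' the smoothed (1-1-1 running mean) intensities are reduced to a baseline
#' (median of the leading samples) and peak; the times of the 25% and 75%
#' crossings of the baseline-to-peak rise are interpolated and the assembly
#' line through them is extrapolated back to the baseline level. For a
#' linear assembly ramp this is unbiased regardless of the assembly rate,
#' which makes onset-referenced timing comparable between strains with
#' different kinetics.
#'
#' @param trajectory A [patch_trajectory()].
#' @param baseline_frames Number of leading samples whose median defines
#'   the baseline; default 15% of the series (at least 3).
#' @return Onset time in seconds, or `NA_real_` when the rise cannot be
#'   bracketed.
#' @export
trajectory_onset <- function(trajectory, baseline_frames = NULL) {
  stopifnot(inherits(trajectory, "patch_trajectory"))
  d <- trajectory$detections
  if (nrow(d) < 5) return(NA_real_)
  dt <- trajectory$frame_interval
  sm <- running_mean_111(d$intensity)
  k <- baseline_frames %||% max(3L, floor(0.15 * nrow(d)))
  bg <- median(sm[seq_len(min(k, nrow(d)))])
  pk_i <- which.max(sm)
  pk <- sm[pk_i]
  if (pk <= bg) return(NA_real_)
  t <- d$frame * dt
  crossing <- function(level) {
    pre <- seq_len(pk_i)
    i <- which(sm[pre] >= level)[1]
    if (is.na(i) || i == 1) return(NA_real_)
    t[i - 1] + (level - sm[i - 1]) / (sm[i] - sm[i - 1]) * (t[i] - t[i - 1])
  }
  t25 <- crossing(bg + 0.25 * (pk - bg))
  t75 <- crossing(bg + 0.75 * (pk - bg))
  if (is.na(t25) || is.na(t75) || t75 <= t25) return(NA_real_)
  t25 - (t75 - t25) / 2
}

#' Robust average of aligned trajectories
#'
#' Aligns each trajectory on a fiducial frame — the frame of patch
#' disappearance (last detection) or of peak intensity — then computes, at
#' every aligned timepoint, the median and consistency-scaled MAD of
#' centroid displacement and of peak-normalized intensity across
#' trajectories. Displacement is measured from each trajectory's position
#' at its own fiducial frame, so the median displacement at the alignment
#' origin is 0.
#'
#' @param trajectories List of >= 3 [patch_trajectory()] objects.
#' @param alignment `"disappearance"` (default, suited to movement
#'   profiles) or `"intensity-peak"` (suited to intensity profiles).
#' @param pixel_size Micrometers per pixel.
#' @return An object of class `movement_profile`: a data.frame with columns
#'   `time` (seconds, 0 at the fiducial), `median_displacement`,
#'   `displacement_mad` (micrometers), `median_intensity`, `intensity_mad`
#'   (peak-normalized), `n` (trajectories contributing).
#' @export
average_trajectories <- function(trajectories,
                                 alignment = c("disappearance",
                                               "intensity-peak"),
                                 pixel_size = 1) {
  alignment <- match.arg(alignment)
  stopifnot(is.list(trajectories))
  if (length(trajectories) < 3)
    .stopf("average_trajectories needs >= 3 trajectories, got %d",
           length(trajectories))
  for (tr in trajectories) stopifnot(inherits(tr, "patch_trajectory"))
  dt <- trajectories[[1]]$frame_interval
  per <- lapply(trajectories, function(tr) {
    d <- tr$detections
    fid <- if (alignment == "disappearance") nrow(d) else which.max(d$intensity)
    disp <- sqrt((d$x - d$x[fid])^2 + (d$y - d$y[fid])^2) * pixel_size
    peak <- max(d$intensity)
    data.frame(rel = d$frame - d$frame[fid], disp = disp,
               inten = if (peak > 0) d$intensity / peak else d$intensity)
  })
  all_rel <- sort(unique(unlist(lapply(per, `[[`, "rel"))))
  out <- data.frame(time = all_rel * dt,
                    median_displacement = NA_real_, displacement_mad = NA_real_,
                    median_intensity = NA_real_, intensity_mad = NA_real_,
                    n = NA_integer_)
  for (i in seq_along(all_rel)) {
    ds <- unlist(lapply(per, function(p) p$disp[p$rel == all_rel[i]]))
    is_ <- unlist(lapply(per, function(p) p$inten[p$rel == all_rel[i]]))
    out$median_displacement[i] <- median(ds)
    out$displacement_mad[i] <- scaled_mad(ds)
    out$median_intensity[i] <- median(is_)
    out$intensity_mad[i] <- scaled_mad(is_)
    out$n[i] <- length(ds)
  }
  class(out) <- c("movement_profile", "data.frame")
  attr(out, "alignment") <- alignment
  attr(out, "frame_interval") <- dt
  out
}

#' @export
plot.movement_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$median_displacement, type = "n",
       xlab = "time from alignment (s)", ylab = "displacement (um)", ...)
  polygon(c(x$time, rev(x$time)),
          c(x$median_displacement - x$displacement_mad,
            rev(x$median_displacement + x$displacement_mad)),
          col = rgb(0.2, 0.4, 0.8, 0.3), border = NA)
  lines(x$time, x$median_displacement, col = "navy", lwd = 2)
  plot(x$time, x$median_intensity, type = "n",
       xlab = "time from alignment (s)", ylab = "intensity (norm.)")
  polygon(c(x$time, rev(x$time)),
          c(x$median_intensity - x$intensity_mad,
            rev(x$median_intensity + x$intensity_mad)),
          col = rgb(0.8, 0.3, 0.2, 0.3), border = NA)
  lines(x$time, x$median_intensity, col = "darkred", lwd = 2)
  invisible(x)
}

#' Kymograph along a line
#'
#' Position-versus-time image: each column is the width-averaged intensity
#' profile along the line in one frame. Sample points are spaced ~1 px
#' along the line; averaging is over `width` parallel lines offset along
#' the normal; intensities are bilinearly interpolated.
#'
#' @param stack ny x nx x n_frames array.
#' @param line Numeric `c(x0, y0, x1, y1)`, 0-based pixel coordinates.
#' @param width Averaging width in pixels (>= 1).
#' @return Matrix (positions along line) x (frames).
#' @export
kymograph <- function(stack, line, width = 1) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, length(line) == 4)
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  dx <- line[3] - line[1]; dy <- line[4] - line[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) .stopf("kymograph line has zero length")
  if (any(line[c(1, 3)] < 0) || any(line[c(1, 3)] > nx - 1) ||
      any(line[c(2, 4)] < 0) || any(line[c(2, 4)] > ny - 1))
    .stopf("kymograph line endpoints outside image bounds")
  npos <- ceiling(len) + 1L
  s <- seq(0, 1, length.out = npos)
  ux <- dx / len; uy <- dy / len       # along-line unit vector
  nxv <- -uy; nyv <- ux                # normal
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(width, 1))
  bilinear <- function(img, x, y) {
    x <- pmin(pmax(x, 0), nx - 1); y <- pmin(pmax(y, 0), ny - 1)
    x0 <- floor(x); y0 <- floor(y)
    x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
    fx <- x - x0; fy <- y - y0
    img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
      img[cbind(y0 + 1, x1 + 1)] * fx * (1 - fy) +
      img[cbind(y1 + 1, x0 + 1)] * (1 - fx) * fy +
      img[cbind(y1 + 1, x1 + 1)] * fx * fy
  }
  out <- matrix(0, npos, nf)
  for (f in seq_len(nf)) {
    img <- stack[, , f]
    acc <- numeric(npos)
    for (o in offs) {
      px <- line[1] + s * dx + o * nxv
      py <- line[2] + s * dy + o * nyv
      acc <- acc + bilinear(img, px, py)
    }
    out[, f] <- acc / length(offs)
  }
  out
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over all frames, visualizing every transient patch of
#' a time lapse at once.
#'
#' @param stack ny x nx x n_frames array (n_frames >= 1).
#' @return Matrix ny x nx.
#' @export
max_projection <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 1)
  out <- stack[, , 1]
  for (f in seq_len(dim(stack)[3])[-1]) out <- pmax(out, stack[, , f])
  out
}
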