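# Particle detection and trajectory linking.
#
# Re-implementation of the commodity single-particle tracking step as
# local-maxima detection with intensity-weighted centroid refinement and
# greedy nearest-neighbour frame-to-frame linking with gap bridging.
# Coordinates follow the image convention: positions are (x, y) with
# x = column, pixel centers at integer coordinates, 0-based; frames are
# 0-based.

#' Detect diffraction-limited spots in one frame
#'
#' Pixels above an intensity cutoff are scanned brightest-first; a
#' candidate is accepted if it is the maximum of its
#' `spot_radius`-neighbourhood and no brighter accepted detection lies
#' within `spot_radius`. Each accepted spot is refined to the
#' intensity-weighted centroid of its local window.
#'
#' The cutoff is the `intensity_percentile` quantile of the frame's
#' background distribution, estimated robustly as
#' `median + qnorm(intensity_percentile) * scaled MAD` so that it does not
#' move with the number of bright patches in the frame; in a noise-free
#' frame (MAD 0) every pixel above the flat background level (the frame
#' minimum) is a candidate.
#'
#' @param frame_image Numeric matrix (one movie frame).
#' @param spot_radius Spot radius in pixels (>= 1); sets the local-maximum
#'   neighbourhood, the minimum separation between detections and the
#'   centroid window.
#' @param intensity_percentile Fraction in (0, 1); background percentile
#'   the cutoff corresponds to.
#' @return data.frame with columns `x`, `y` (0-based sub-pixel positions,
#'   x = column) and `intensity` (background-subtracted summed window
#'   intensity). Zero rows for flat or empty images.
#' @export
detect_particles <- function(frame_image, spot_radius = 3,
                             intensity_percentile = 0.9995) {
  stopifnot(is.matrix(frame_image), .is_num1(spot_radius), spot_radius >= 1,
            .is_num1(intensity_percentile),
            intensity_percentile > 0, intensity_percentile < 1)
  empty <- data.frame(x = numeric(), y = numeric(), intensity = numeric())
  rng <- range(frame_image)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(empty)
  r <- as.integer(round(spot_radius))
  smad <- scaled_mad(as.numeric(frame_image))
  # robust background cutoff; a noise-free frame (MAD 0) sits at its flat
  # background level, so anything above the minimum is signal
  thr <- if (smad > 0)
    median(frame_image) + stats::qnorm(intensity_percentile) * smad
  else
    rng[1]
  cand <- which(frame_image > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  vals <- frame_image[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  ny0 <- nrow(frame_image); nx0 <- ncol(frame_image)
  # brightest-first: keep neighbourhood maxima separated by >= spot_radius
  keep <- logical(nrow(cand))
  kept_y <- numeric(0); kept_x <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    yi <- cand[i, 1]; xi <- cand[i, 2]
    win <- frame_image[max(1, yi - r):min(ny0, yi + r),
                       max(1, xi - r):min(nx0, xi + r)]
    if (frame_image[yi, xi] < max(win)) next
    if (length(kept_y) == 0 ||
        all((kept_y - yi)^2 + (kept_x - xi)^2 >= spot_radius^2)) {
      keep[i] <- TRUE
      kept_y <- c(kept_y, yi); kept_x <- c(kept_x, xi)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  ny <- nrow(frame_image); nx <- ncol(frame_image)
  out <- data.frame(x = numeric(nrow(cand)), y = numeric(nrow(cand)),
                    intensity = numeric(nrow(cand)))
  for (i in seq_len(nrow(cand))) {
    yi <- cand[i, 1]; xi <- cand[i, 2]
    ys <- max(1, yi - r):min(ny, yi + r)
    xs <- max(1, xi - r):min(nx, xi + r)
    win <- frame_image[ys, xs, drop = FALSE]
    w <- win - min(win)
    sw <- sum(w)
    if (sw <= 0) { cx <- xi; cy <- yi } else {
      cy <- sum(rowSums(w) * ys) / sw
      cx <- sum(colSums(w) * xs) / sw
    }
    out$x[i] <- cx - 1  # to 0-based
    out$y[i] <- cy - 1
    out$intensity[i] <- sw
  }
  out[order(out$y, out$x), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack ny x nx x n_frames array, or a `rendered_movie`.
#' @inheritParams detect_particles
#' @return data.frame with columns `frame` (0-based), `x`, `y`, `intensity`.
#' @export
detect_stack <- function(stack, spot_radius = 3, intensity_percentile = 0.9995) {
  if (inherits(stack, "rendered_movie")) stack <- stack$stack
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  res <- lapply(seq_len(dim(stack)[3]), function(f) {
    d <- detect_particles(stack[, , f], spot_radius, intensity_percentile)
    if (nrow(d)) cbind(frame = f - 1L, d) else
      data.frame(frame = integer(), x = numeric(), y = numeric(),
                 intensity = numeric())
  })
  do.call(rbind, res)
}

#' Link detections into trajectories (greedy nearest neighbour)
#'
#' Frame-to-frame assignment: candidate (track, detection) pairs within
#' `max_displacement` are linked closest-pair-first; among equidistant
#' candidates the lowest patch id wins. Tracks missing up to `max_gap`
#' consecutive frames remain linkable (gap bridging). Unmatched detections
#' start new trajectories, so every detection belongs to exactly one
#' trajectory.
#'
#' @param detections data.frame with columns `frame` (0-based), `x`, `y`,
#'   `intensity`, sorted or not.
#' @param max_displacement Maximum frame-to-frame link distance, pixels.
#' @param max_gap Maximum number of bridged missing frames (default 0).
#' @param frame_interval Seconds per frame, attached to the trajectories.
#' @return List of [patch_trajectory()] objects.
#' @export
link_trajectories <- function(detections, max_displacement, max_gap = 0,
                              frame_interval = 1) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x", "y", "intensity") %in% names(detections)),
            .is_num1(max_displacement), max_displacement > 0,
            .is_count(max_gap))
  det <- detections[order(detections$frame), , drop = FALSE]
  tracks <- list()   # each: list(id, last_x, last_y, last_frame, rows)
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- det[det$frame == f, , drop = FALSE]
    nd <- nrow(rows)
    active <- which(vapply(tracks, function(tr)
      f - tr$last_frame >= 1 && f - tr$last_frame <= max_gap + 1,
      logical(1)))
    # candidate pairs within range
    if (length(active) && nd) {
      cand <- expand.grid(ti = active, di = seq_len(nd))
      cand$dist <- sqrt(
        (vapply(tracks[cand$ti], `[[`, numeric(1), "last_x") - rows$x[cand$di])^2 +
        (vapply(tracks[cand$ti], `[[`, numeric(1), "last_y") - rows$y[cand$di])^2)
      cand <- cand[cand$dist <= max_displacement, , drop = FALSE]
      cand$id <- vapply(tracks[cand$ti], `[[`, integer(1), "id")
      cand <- cand[order(cand$dist, cand$id, cand$di), , drop = FALSE]
      used_t <- integer(0); used_d <- integer(0)
      for (i in seq_len(nrow(cand))) {
        ti <- cand$ti[i]; di <- cand$di[i]
        if (ti %in% used_t || di %in% used_d) next
        tr <- tracks[[ti]]
        tr$rows[[length(tr$rows) + 1L]] <- rows[di, , drop = FALSE]
        tr$last_x <- rows$x[di]; tr$last_y <- rows$y[di]; tr$last_frame <- f
        tracks[[ti]] <- tr
        used_t <- c(used_t, ti); used_d <- c(used_d, di)
      }
    } else used_d <- integer(0)
    for (di in setdiff(seq_len(nd), used_d)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, last_x = rows$x[di], last_y = rows$y[di],
        last_frame = f, rows = list(rows[di, , drop = FALSE]))
      next_id <- next_id + 1L
    }
  }
  lapply(tracks[order(vapply(tracks, `[[`, integer(1), "id"))], function(tr) {
    df <- do.call(rbind, tr$rows)
    patch_trajectory(df[, c("frame", "x", "y", "intensity")], id = tr$id,
                     frame_interval = frame_interval)
  })
}

#' Detect and track a whole movie
#'
#' Convenience wrapper: [detect_stack()] followed by [link_trajectories()].
#'
#' @inheritParams detect_stack
#' @inheritParams link_trajectories
#' @param min_frames Drop trajectories with fewer detections (noise tracks);
#'   default 1 keeps everything.
#' @return List of [patch_trajectory()] objects.
#' @export
track_movie <- function(stack, spot_radius = 3, intensity_percentile = 0.9995,
                        max_displacement = 3, max_gap = 1,
                        frame_interval = NULL, min_frames = 1) {
  if (inherits(stack, "rendered_movie")) {
    frame_interval <- frame_interval %||% stack$frame_interval
    stack <- stack$stack
  }
  frame_interval <- frame_interval %||% 1
  det <- detect_stack(stack, spot_radius, intensity_percentile)
  trajs <- link_trajectories(det, max_displacement, max_gap, frame_interval)
  trajs[vapply(trajs, function(tr) nrow(tr$detections) >= min_frames,
               logical(1))]
}
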