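# Epifluorescence peak-intensity pipeline: image preprocessing
# (rolling-ball background, simple-ratio bleach correction), 1-1-1
# running-mean smoothing, median-of-minima background, peak statistics and
# per-dataset scaling.

# grayscale erosion/dilation with a non-flat ball-cap element, computed by
# looping over kernel offsets on a padded matrix
.ball_kernel <- function(radius, height) {
  r <- ceiling(radius)
  d <- outer((-r:r)^2, (-r:r)^2, `+`)
  k <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)  # NA: outside support
  inside <- d <= radius^2
  k[inside] <- height * sqrt(1 - d[inside] / radius^2)
  k
}

.gray_morph <- function(img, kernel, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- (nrow(kernel) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(if (op == "erode") Inf else -Inf, ny + 2 * r, nx + 2 * r)
  pad[r + seq_len(ny), r + seq_len(nx)] <- img
  out <- matrix(if (op == "erode") Inf else -Inf, ny, nx)
  for (dy in -r:r) for (dx in -r:r) {
    h <- kernel[dy + r + 1, dx + r + 1]
    if (is.na(h)) next
    shifted <- pad[r + dy + seq_len(ny), r + dx + seq_len(nx)]
    out <- if (op == "erode") pmin(out, shifted - h)
           else pmax(out, shifted + h)
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' opening (erosion followed by dilation) with a ball-cap structuring
#' element — the morphological equivalent of the classic rolling-ball
#' algorithm — and subtracts it. The cap's lateral radius is `ball_radius`
#' pixels; its height in intensity units is decoupled from the radius
#' (default 5% of the image's dynamic range) so that the ball rolls under
#' diffraction-limited spots instead of penetrating them. Since the opening
#' never exceeds the image, the result is non-negative.
#'
#' @param frame_image Numeric matrix.
#' @param ball_radius Ball radius in pixels (>= 1, smaller than the image).
#' @param ball_height Cap height in intensity units; default
#'   `0.05 * diff(range(frame_image))` (0 gives a flat disc).
#' @return Background-subtracted image (same dimensions, all values >= 0).
#' @export
rolling_ball_background <- function(frame_image, ball_radius = 25,
                                    ball_height = NULL) {
  stopifnot(is.matrix(frame_image), .is_num1(ball_radius), ball_radius >= 1)
  if (2 * ball_radius + 1 > min(dim(frame_image)))
    .stopf("ball radius %g too large for a %dx%d image", ball_radius,
           nrow(frame_image), ncol(frame_image))
  ball_height <- ball_height %||% (0.05 * diff(range(frame_image)))
  k <- .ball_kernel(ball_radius, ball_height)
  bg <- .gray_morph(.gray_morph(frame_image, k, "erode"), k, "dilate")
  frame_image - bg
}

#' Simple-ratio photobleaching correction
#'
#' Multiplies every frame by `mean(frame_1) / mean(frame_t)` so that all
#' corrected frame means equal the first frame's mean. Idempotent.
#'
#' @param stack ny x nx x n_frames array (n_frames >= 2), all frame means
#'   positive.
#' @return Corrected stack of the same dimensions.
#' @export
bleach_correct_simple_ratio <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 2)
  mu <- apply(stack, 3, mean)
  if (any(mu <= 0))
    .stopf("simple-ratio bleach correction needs positive frame means; frame %d has mean %.3g",
           which(mu <= 0)[1], mu[mu <= 0][1])
  out <- stack
  for (f in seq_along(mu)) out[, , f] <- stack[, , f] * (mu[1] / mu[f])
  out
}

#' Running mean with a 1-1-1 kernel
#'
#' Centered three-point moving average; at the two edges the mean of the
#' two available samples is used.
#'
#' @param values Numeric vector (>= 3 samples).
#' @return Smoothed vector of the same length.
#' @export
#' @examples
#' running_mean_111(c(0, 3, 0))  # 1.5 1.0 1.5
running_mean_111 <- function(values) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 3) .stopf("running mean needs >= 3 samples, got %d", n)
  out <- numeric(n)
  out[1] <- mean(values[1:2])
  out[n] <- mean(values[(n - 1):n])
  out[2:(n - 1)] <- (values[1:(n - 2)] + values[2:(n - 1)] + values[3:n]) / 3
  out
}

#' Cytoplasmic background from trajectory minima
#'
#' The background of an epifluorescence dataset is estimated as the median,
#' over trajectories, of each trajectory's lowest (smoothed) fluorescence
#' intensity.
#'
#' @param intensity_series List of numeric vectors (one smoothed intensity
#'   series per trajectory; >= 1 trajectory).
#' @return Scalar background level.
#' @export
median_minima_background <- function(intensity_series) {
  stopifnot(is.list(intensity_series), length(intensity_series) >= 1)
  median(vapply(intensity_series, min, numeric(1)))
}

#' Per-trajectory peak records
#'
#' Applies the epifluorescence peak pipeline to a set of trajectories from
#' one strain and experiment: 1-1-1 running-mean smoothing of each
#' trajectory's intensity series, background estimation as the median of
#' per-trajectory minima, and the peak of each smoothed series. Corrected
#' peaks (`raw_peak - background`) may be negative; they are reported, not
#' clamped.
#'
#' @param trajectories List of [patch_trajectory()] objects or a
#'   `trajectory_set`.
#' @param strain,experiment Labels attached to the records.
#' @return data.frame of class `peak_records`: `strain`, `experiment`,
#'   `patch_id`, `raw_peak`, `background`, `corrected_peak`.
#' @export
peak_records <- function(trajectories, strain = "strain",
                         experiment = "exp1") {
  if (inherits(trajectories, "trajectory_set"))
    trajectories <- trajectories$trajectories
  stopifnot(is.list(trajectories), length(trajectories) >= 1)
  smoothed <- lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "patch_trajectory"))
    running_mean_111(tr$detections$intensity)
  })
  bg <- median_minima_background(smoothed)
  out <- data.frame(
    strain = strain, experiment = experiment,
    patch_id = vapply(trajectories, function(tr) as.integer(tr$id),
                      integer(1)),
    raw_peak = vapply(smoothed, max, numeric(1)),
    background = bg)
  out$corrected_peak <- out$raw_peak - out$background
  class(out) <- c("peak_records", "data.frame")
  out
}

#' Scale peak intensities within experiments and average across them
#'
#' Within each experiment (dataset), per-strain mean and SD of the
#' corrected peaks are computed and all means are divided by the
#' experiment's highest strain mean (so the brightest strain of every
#' experiment is exactly 1.0); SDs are divided by the same factor. Across
#' experiments, the per-strain mean of the scaled means and the average of
#' the scaled SDs are reported.
#'
#' @param peaks A `peak_records` data.frame (possibly rbind-ed over strains
#'   and experiments) with columns `strain`, `experiment`,
#'   `corrected_peak`.
#' @return data.frame of class `strain_intensity_summary`: `strain`,
#'   `mean_peak_AU`, `sd_AU`, `n_events`, `n_experiments`.
#' @export
scale_dataset <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("strain", "experiment", "corrected_peak") %in% names(peaks)))
  if (nrow(peaks) == 0) .stopf("empty dataset: no peak records")
  per_exp <- list()
  for (e in unique(peaks$experiment)) {
    sub <- peaks[peaks$experiment == e, , drop = FALSE]
    if (nrow(sub) == 0) .stopf("experiment '%s' contains no peak records", e)
    mu <- tapply(sub$corrected_peak, sub$strain, mean)
    s <- tapply(sub$corrected_peak, sub$strain, sd)
    s[is.na(s)] <- 0
    n <- tapply(sub$corrected_peak, sub$strain, length)
    top <- max(mu)
    if (top <= 0)
      .stopf("experiment '%s': highest strain mean peak is %.3g; cannot scale",
             e, top)
    per_exp[[as.character(e)]] <- data.frame(
      strain = names(mu), scaled_mean = as.numeric(mu) / top,
      scaled_sd = as.numeric(s) / top, n = as.integer(n))
  }
  all_strains <- unique(peaks$strain)
  out <- data.frame(strain = all_strains, mean_peak_AU = NA_real_,
                    sd_AU = NA_real_, n_events = NA_integer_,
                    n_experiments = NA_integer_)
  for (i in seq_along(all_strains)) {
    st <- all_strains[i]
    rows <- lapply(per_exp, function(d) d[d$strain == st, , drop = FALSE])
    rows <- do.call(rbind, rows)
    out$mean_peak_AU[i] <- mean(rows$scaled_mean)
    out$sd_AU[i] <- mean(rows$scaled_sd)
    out$n_events[i] <- sum(rows$n)
    out$n_experiments[i] <- nrow(rows)
  }
  class(out) <- c("strain_intensity_summary", "data.frame")
  out
}
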