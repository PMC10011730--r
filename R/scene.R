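#' Synthetic microscopy scene description
#'
#' A ground-truth record of a synthetic time-lapse: cell geometry, the
#' patches with their per-channel kinetics, motion and true class, and the
#' acquisition/rendering parameters. [render_movie()] turns a scene into an
#' image stack plus ground-truth tables.
#'
#' @param patches List of patch descriptions; each element is a list with
#'   `kinetics` (a [patch_kinetics()]), `x`, `y` (start position,
#'   micrometers), and optionally `class` (one of `"persistent-PM"`,
#'   `"transient-PM"`, `"cytoplasmic"`), `cell` (cell index),
#'   `motion` (list: `lateral_sigma` um/frame, `inward_displacement` um,
#'   `inward_duration` s, `scission_time` absolute s or `NA`).
#' @param cells Optional data.frame with columns `x`, `y`, `radius`
#'   (micrometers).
#' @param frame_interval Seconds per frame.
#' @param n_frames Number of frames (>= 2).
#' @param image_size `c(ny, nx)` pixels.
#' @param pixel_size Micrometers per pixel (> 0).
#' @param psf_sigma SD of the isotropic Gaussian point-spread function,
#'   micrometers.
#' @param noise_sigma SD of additive Gaussian camera noise, intensity units.
#' @param bleach_rate Exponential photobleaching rate, per second.
#' @param background Diffuse constant background level, intensity units.
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical rendering.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(patches, cells = NULL, frame_interval = 1,
                            n_frames, image_size = c(64, 64),
                            pixel_size = 0.1, psf_sigma = 0.15,
                            noise_sigma = 0.01, bleach_rate = 0,
                            background = 0.1, seed = 1) {
  stopifnot(is.list(patches), .is_count(n_frames))
  if (n_frames < 2) .stopf("a scene needs n_frames >= 2")
  if (pixel_size <= 0) .stopf("pixel_size must be > 0")
  for (p in patches)
    stopifnot(inherits(p$kinetics, "patch_kinetics"),
              .is_num1(p$x), .is_num1(p$y))
  structure(list(patches = patches, cells = cells,
                 frame_interval = frame_interval, n_frames = n_frames,
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 noise_sigma = noise_sigma, bleach_rate = bleach_rate,
                 background = background, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d patches, %d frames @ %g s, %dx%d px (%g um/px), seed %d\n",
              length(x$patches), x$n_frames, x$frame_interval,
              x$image_size[1], x$image_size[2], x$pixel_size, x$seed))
  invisible(x)
}

#' Build a renderable scene from a strain preset
#'
#' Lays `n_events` patches of a [patch_preset()] out on a grid (spacing
#' chosen so neighbouring diffraction-limited spots do not overlap), with
#' per-event onset jitter and amplitude variability drawn from the preset.
#'
#' @param preset A `patch_preset` or preset name.
#' @param n_events Number of patches.
#' @param seed Integer seed.
#' @param spacing Grid spacing, micrometers.
#' @param noise_sigma,pixel_size,psf_sigma,bleach_rate,background Rendering
#'   parameters (see [synthetic_scene()]).
#' @return A `synthetic_scene`.
#' @export
scene_from_preset <- function(preset, n_events, seed = 1, spacing = 3,
                              noise_sigma = 0.01, pixel_size = 0.1,
                              psf_sigma = 0.15, bleach_rate = 0,
                              background = 0.1) {
  if (is.character(preset)) preset <- patch_preset(preset)
  stopifnot(inherits(preset, "patch_preset"), .is_count(n_events),
            n_events >= 1)
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_events))
  nrow_grid <- ceiling(n_events / ncol_grid)
  margin <- spacing
  patches <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    r <- (i - 1) %/% ncol_grid
    cc <- (i - 1) %% ncol_grid
    onset <- preset$onset_mean +
      runif(1, -preset$onset_jitter, preset$onset_jitter)
    amp <- max(rnorm(1, preset$amplitude, preset$amplitude_sd),
               0.05 * preset$amplitude)
    patches[[i]] <- list(
      kinetics = patch_kinetics(onset, preset$assembly, preset$plateau,
                                preset$disassembly, amp, baseline = 0),
      x = margin + cc * spacing, y = margin + r * spacing,
      class = "transient-PM",
      motion = list(lateral_sigma = preset$motion$lateral_sigma,
                    inward_displacement = preset$motion$inward_displacement,
                    inward_duration = preset$motion$inward_duration,
                    scission_time = if (is.finite(preset$motion$scission_offset))
                      onset + preset$motion$scission_offset else NA_real_))
  }
  side_x <- 2 * margin + (ncol_grid - 1) * spacing
  side_y <- 2 * margin + (nrow_grid - 1) * spacing
  n_frames <- ceiling(preset$onset_mean + preset$onset_jitter +
                        preset$lifetime + 10)
  synthetic_scene(patches,
                  frame_interval = preset$frame_interval,
                  n_frames = n_frames,
                  image_size = c(ceiling(side_y / pixel_size) + 1,
                                 ceiling(side_x / pixel_size) + 1),
                  pixel_size = pixel_size, psf_sigma = psf_sigma,
                  noise_sigma = noise_sigma, bleach_rate = bleach_rate,
                  background = background, seed = seed)
}

#' Render a scene into an image stack with ground truth
#'
#' Each patch is rendered as an isotropic Gaussian spot (peak height equal
#' to its template intensity, SD `psf_sigma`) at its per-frame position;
#' diffuse background is added, the whole frame is multiplied by
#' `exp(-bleach_rate * t)`, and Gaussian camera noise is added. Patch
#' positions outside the field of view trigger a warning and are clipped
#' when stamped.
#'
#' @param scene A [synthetic_scene()].
#' @return List of class `rendered_movie`: `stack` (array ny x nx x
#'   n_frames), `truth` (one row per patch: patch_id, class, x, y, onset,
#'   lifetime, amplitude, scission_time), `truth_frames` (one row per patch
#'   and frame: patch_id, frame, x, y, intensity), `frame_interval`,
#'   `pixel_size`, `scene`.
#' @export
render_movie <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(scene$seed)
  ny <- scene$image_size[1]; nx <- scene$image_size[2]
  nf <- scene$n_frames
  dt <- scene$frame_interval
  px <- scene$pixel_size
  sig_px <- scene$psf_sigma / px
  t <- (0:(nf - 1)) * dt
  npat <- length(scene$patches)

  # per-patch per-frame ground truth (positions in micrometers)
  pos_x <- matrix(NA_real_, nf, max(npat, 1))
  pos_y <- matrix(NA_real_, nf, max(npat, 1))
  intens <- matrix(0, nf, max(npat, 1))
  clipped <- FALSE
  for (j in seq_len(npat)) {
    p <- scene$patches[[j]]
    mo <- p$motion %||% list(lateral_sigma = 0, inward_displacement = 0,
                             inward_duration = 1, scission_time = NA_real_)
    x <- rep(p$x, nf); y <- rep(p$y, nf)
    if ((mo$lateral_sigma %||% 0) > 0) {
      x <- x + cumsum(rnorm(nf, 0, mo$lateral_sigma))
      y <- y + cumsum(rnorm(nf, 0, mo$lateral_sigma))
    }
    if (is.finite(mo$scission_time %||% NA_real_)) {
      th <- runif(1, 0, 2 * pi)
      ramp <- pmin(pmax((t - mo$scission_time) / mo$inward_duration, 0), 1) *
        mo$inward_displacement
      x <- x + cos(th) * ramp
      y <- y + sin(th) * ramp
    }
    pos_x[, j] <- x; pos_y[, j] <- y
    intens[, j] <- kinetic_template(p$kinetics, t)
    if (any(x < 0 | x > (nx - 1) * px | y < 0 | y > (ny - 1) * px))
      clipped <- TRUE
  }
  if (clipped)
    warning("some patch positions fall outside the field of view; spots clipped",
            call. = FALSE)

  stack <- array(0, dim = c(ny, nx, nf))
  half <- ceiling(4 * sig_px)
  for (f in seq_len(nf)) {
    img <- matrix(scene$background, ny, nx)
    for (j in seq_len(npat)) {
      a <- intens[f, j]
      if (a <= 0) next
      cx <- pos_x[f, j] / px; cy <- pos_y[f, j] / px  # 0-based px coords
      i0 <- max(floor(cy) - half, 0); i1 <- min(ceiling(cy) + half, ny - 1)
      j0 <- max(floor(cx) - half, 0); j1 <- min(ceiling(cx) + half, nx - 1)
      if (i0 > i1 || j0 > j1) next
      yy <- i0:i1; xx <- j0:j1
      gy <- exp(-((yy - cy)^2) / (2 * sig_px^2))
      gx <- exp(-((xx - cx)^2) / (2 * sig_px^2))
      img[yy + 1, xx + 1] <- img[yy + 1, xx + 1] + a * outer(gy, gx)
    }
    img <- img * exp(-scene$bleach_rate * t[f])
    if (scene$noise_sigma > 0)
      img <- img + matrix(rnorm(ny * nx, 0, scene$noise_sigma), ny, nx)
    stack[, , f] <- img
  }

  truth <- data.frame(
    patch_id = seq_len(npat),
    class = vapply(scene$patches, function(p) p$class %||% NA_character_,
                   character(1)),
    x = vapply(scene$patches, function(p) p$x, numeric(1)),
    y = vapply(scene$patches, function(p) p$y, numeric(1)),
    onset = vapply(scene$patches, function(p) p$kinetics$onset_time,
                   numeric(1)),
    lifetime = vapply(scene$patches, function(p) kinetics_lifetime(p$kinetics),
                      numeric(1)),
    amplitude = vapply(scene$patches, function(p) p$kinetics$amplitude,
                       numeric(1)),
    scission_time = vapply(scene$patches, function(p)
      (p$motion %||% list())$scission_time %||% NA_real_, numeric(1)))
  truth_frames <- if (npat > 0) data.frame(
    patch_id = rep(seq_len(npat), each = nf),
    frame = rep(0:(nf - 1), npat),
    x = as.vector(pos_x[, seq_len(npat)]),
    y = as.vector(pos_y[, seq_len(npat)]),
    intensity = as.vector(intens[, seq_len(npat)]))
  else data.frame(patch_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), intensity = numeric())

  structure(list(stack = stack, truth = truth, truth_frames = truth_frames,
                 frame_interval = dt, pixel_size = px, scene = scene),
            class = "rendered_movie")
}

#' @export
print.rendered_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<rendered_movie> %dx%d px, %d frames @ %g s, %d patches\n",
              d[1], d[2], d[3], x$frame_interval, nrow(x$truth)))
  invisible(x)
}
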