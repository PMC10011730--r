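# Patch classification: persistent / transient plasma-membrane patches vs
# cytoplasmic patches, per-cell summaries, and scission detection from the
# Rvs167 signature (rapid intensity drop + inward centroid movement).

#' Cell geometry record
#'
#' @param x,y Cell center, micrometers.
#' @param radius Cell radius, micrometers (> 0).
#' @param cell_id Identifier.
#' @param membrane_band Width of the membrane-associated band inside the
#'   cell boundary, micrometers (default 0.3).
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(x, y, radius, cell_id = 1L, membrane_band = 0.3) {
  stopifnot(.is_num1(x), .is_num1(y), .is_num1(radius), radius > 0,
            .is_num1(membrane_band), membrane_band > 0)
  structure(list(cell_id = cell_id, x = x, y = y, radius = radius,
                 membrane_band = membrane_band),
            class = "cell_record")
}

#' Classify one patch trajectory
#'
#' Rules, applied in order: a trajectory whose median radial position lies
#' outside the cell is `"unassigned"`; one whose median distance to the
#' cell boundary exceeds the membrane band is `"cytoplasmic"`; otherwise it
#' is `"persistent-PM"` if its lifetime is at least
#' `persistence_fraction * movie_duration`, `"transient-PM"` if it spans at
#' least `min_frames` frames, and `"discarded"` (noise) below that.
#'
#' @param trajectory A [patch_trajectory()] (positions in micrometers, or
#'   supply `pixel_size`).
#' @param cell A [cell_record()].
#' @param movie_duration Movie length, seconds.
#' @param persistence_fraction Lifetime fraction of the movie above which a
#'   membrane patch counts as persistent (default 0.9).
#' @param min_frames Minimum detections for a transient patch (default 3).
#' @param pixel_size Micrometers per pixel of the trajectory coordinates
#'   (default 1: already micrometers).
#' @return One of `"persistent-PM"`, `"transient-PM"`, `"cytoplasmic"`,
#'   `"discarded"`, `"unassigned"`.
#' @export
assign_patch_class <- function(trajectory, cell, movie_duration,
                               persistence_fraction = 0.9, min_frames = 3,
                               pixel_size = 1) {
  stopifnot(inherits(trajectory, "patch_trajectory"),
            inherits(cell, "cell_record"), .is_num1(movie_duration),
            movie_duration > 0)
  d <- trajectory$detections
  r <- sqrt((d$x * pixel_size - cell$x)^2 + (d$y * pixel_size - cell$y)^2)
  med_r <- median(r)
  if (med_r > cell$radius) return("unassigned")
  if (cell$radius - med_r > cell$membrane_band) return("cytoplasmic")
  lt <- lifetime(trajectory)
  if (lt >= persistence_fraction * movie_duration) return("persistent-PM")
  if (nrow(d) >= min_frames) return("transient-PM")
  "discarded"
}

#' Per-cell patch-class summary
#'
#' For each class, the fraction of cells exhibiting at least one patch of
#' that class (classes co-occur, so fractions may sum to more than 1), plus
#' the mean number of classified patches per cell.
#'
#' @param assignments data.frame with columns `cell_id` and `class` (one
#'   row per classified trajectory; `"discarded"`/`"unassigned"` rows are
#'   ignored).
#' @param cells List of [cell_record()]s (>= 1), or the number of cells.
#' @param condition Condition label.
#' @return One-row data.frame of class `patch_class_summary`: `condition`,
#'   `n_cells`, `fraction_persistent_pm`, `fraction_transient_pm`,
#'   `fraction_cytoplasmic`, `patches_per_cell`.
#' @export
summarize_cells <- function(assignments, cells, condition = "condition") {
  stopifnot(is.data.frame(assignments),
            all(c("cell_id", "class") %in% names(assignments)))
  n_cells <- if (is.numeric(cells)) as.integer(cells) else length(cells)
  if (n_cells < 1) .stopf("summarize_cells needs >= 1 cell")
  keep <- assignments$class %in% c("persistent-PM", "transient-PM",
                                   "cytoplasmic")
  a <- assignments[keep, , drop = FALSE]
  frac <- function(cls)
    length(unique(a$cell_id[a$class == cls])) / n_cells
  out <- data.frame(condition = condition, n_cells = n_cells,
                    fraction_persistent_pm = frac("persistent-PM"),
                    fraction_transient_pm = frac("transient-PM"),
                    fraction_cytoplasmic = frac("cytoplasmic"),
                    patches_per_cell = nrow(a) / n_cells)
  class(out) <- c("patch_class_summary", "data.frame")
  out
}

#' Detect a scission-like event in a trajectory
#'
#' Vesicle scission shows as a rapid inward centroid movement coinciding
#' with a collapse of the fluorescence signal. The detector returns the
#' earliest frame at which the centroid displacement rate exceeds
#' `displacement_rate_threshold` AND the (smoothed) intensity has fallen
#' below `intensity_drop_fraction` of its peak; `NA` if that never happens.
#'
#' @param trajectory A [patch_trajectory()] (positions micrometers, or use
#'   `pixel_size`).
#' @param displacement_rate_threshold Micrometers per second (default
#'   0.05).
#' @param intensity_drop_fraction Fraction of the peak the intensity must
#'   have dropped below (default 0.9).
#' @param pixel_size Micrometers per pixel of the coordinates.
#' @return Scission time in seconds, or `NA_real_`. The time is refined
#'   below the frame interval by linearly interpolating when the smoothed
#'   intensity crossed the drop level within the qualifying step, so that
#'   timing differences between conditions are not quantized to whole
#'   frames.
#' @export
detect_scission <- function(trajectory, displacement_rate_threshold = 0.05,
                            intensity_drop_fraction = 0.9, pixel_size = 1) {
  stopifnot(inherits(trajectory, "patch_trajectory"))
  d <- trajectory$detections
  if (nrow(d) < 3) return(NA_real_)
  dt <- trajectory$frame_interval
  sm <- running_mean_111(d$intensity)
  peak <- max(sm)
  level <- intensity_drop_fraction * peak
  step <- sqrt(diff(d$x)^2 + diff(d$y)^2) * pixel_size /
    (diff(d$frame) * dt)
  # frame i (2..n) qualifies if the step into it is fast and the intensity
  # at it has dropped below the fraction of peak
  hit <- which(step > displacement_rate_threshold & sm[-1] < level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1] + 1L  # row of the qualifying frame
  t_hit <- d$frame[i] * dt
  # sub-frame refinement: interpolate the downward crossing of the drop
  # level in the step entering the qualifying frame
  if (i > 1 && sm[i - 1] >= level && sm[i - 1] > sm[i]) {
    t_prev <- d$frame[i - 1] * dt
    return(t_prev + (sm[i - 1] - level) / (sm[i - 1] - sm[i]) *
             (t_hit - t_prev))
  }
  t_hit
}

#' Simulate a cell population with known class probabilities
#'
#' Ground-truth generator for the per-cell classification summaries: cells
#' are disks laid out on a grid; each cell independently receives a
#' persistent-PM patch, a transient-PM patch, and a cytoplasmic patch with
#' the given probabilities. Membrane patches sit inside the membrane band;
#' cytoplasmic patches sit well inside the cell; persistent patches span
#' the whole movie, transient ones a patch-lifetime's worth of frames.
#'
#' @param n_cells Number of cells.
#' @param class_probs Named or positional numeric of length 3: probability
#'   that a cell has >= 1 persistent-PM, transient-PM, cytoplasmic patch.
#' @param movie_duration Movie length, seconds (default 290, matching
#'   4 min 50 s classification movies).
#' @param frame_interval Seconds per frame (default 10).
#' @param cell_radius Micrometers (default 2).
#' @param membrane_band Micrometers (default 0.3).
#' @param transient_lifetime Lifetime of transient patches, seconds
#'   (default 30).
#' @param seed Integer seed.
#' @return List of class `cell_population`: `cells` (list of
#'   [cell_record()]), `trajectories` (list of [patch_trajectory()]),
#'   `cell_of` (integer vector: cell index per trajectory), `truth`
#'   (data.frame: trajectory id, cell_id, true class).
#' @export
simulate_cell_population <- function(n_cells, class_probs = c(0.8, 0.3, 0.5),
                                     movie_duration = 290,
                                     frame_interval = 10, cell_radius = 2,
                                     membrane_band = 0.3,
                                     transient_lifetime = 30, seed = 1) {
  stopifnot(.is_count(n_cells), n_cells >= 1, length(class_probs) == 3,
            all(class_probs >= 0 & class_probs <= 1))
  set.seed(seed)
  n_frames <- floor(movie_duration / frame_interval) + 1
  grid <- ceiling(sqrt(n_cells))
  spacing <- 3 * cell_radius
  cells <- vector("list", n_cells)
  trajs <- list(); cell_of <- integer(0); truth <- list()
  tid <- 0L
  classes <- c("persistent-PM", "transient-PM", "cytoplasmic")
  for (ci in seq_len(n_cells)) {
    cx <- spacing * ((ci - 1) %% grid + 1)
    cy <- spacing * ((ci - 1) %/% grid + 1)
    cells[[ci]] <- cell_record(cx, cy, cell_radius, cell_id = ci,
                               membrane_band = membrane_band)
    has <- runif(3) < class_probs
    for (k in which(has)) {
      tid <- tid + 1L
      th <- runif(1, 0, 2 * pi)
      rr <- switch(classes[k],
                   "persistent-PM" = cell_radius - membrane_band / 3,
                   "transient-PM" = cell_radius - membrane_band / 3,
                   "cytoplasmic" = cell_radius / 2 - membrane_band)
      px <- cx + rr * cos(th); py <- cy + rr * sin(th)
      frames <- if (classes[k] == "persistent-PM") 0:(n_frames - 1) else {
        nfr <- max(3, round(transient_lifetime / frame_interval))
        f0 <- sample.int(n_frames - nfr, 1) - 1L
        f0:(f0 + nfr - 1)
      }
      jit <- 0.02
      trajs[[tid]] <- patch_trajectory(
        data.frame(frame = frames,
                   x = px + rnorm(length(frames), 0, jit),
                   y = py + rnorm(length(frames), 0, jit),
                   intensity = 1 + rnorm(length(frames), 0, 0.05)),
        id = tid, frame_interval = frame_interval)
      cell_of[tid] <- ci
      truth[[tid]] <- data.frame(patch_id = tid, cell_id = ci,
                                 true_class = classes[k])
    }
  }
  structure(list(cells = cells, trajectories = trajs, cell_of = cell_of,
                 truth = if (length(truth)) do.call(rbind, truth) else
                   data.frame(patch_id = integer(), cell_id = integer(),
                              true_class = character())),
            class = "cell_population")
}

#' Classify a whole population and summarize per cell
#'
#' Applies [assign_patch_class()] to every trajectory of a
#' [simulate_cell_population()] result (or equivalent structure) and
#' returns both the per-trajectory assignments and the per-cell summary.
#'
#' @param population A `cell_population`.
#' @param movie_duration Movie length, seconds; defaults to the span of the
#'   longest trajectory.
#' @param condition Condition label for the summary.
#' @inheritParams assign_patch_class
#' @return List: `assignments` (data.frame patch_id, cell_id, class),
#'   `summary` ([summarize_cells()] output).
#' @export
classify_population <- function(population, movie_duration = NULL,
                                condition = "condition",
                                persistence_fraction = 0.9, min_frames = 3,
                                pixel_size = 1) {
  stopifnot(inherits(population, "cell_population"))
  trajs <- population$trajectories
  if (is.null(movie_duration))
    movie_duration <- max(vapply(trajs, lifetime, numeric(1)))
  cls <- character(length(trajs))
  for (i in seq_along(trajs))
    cls[i] <- assign_patch_class(trajs[[i]],
                                 population$cells[[population$cell_of[i]]],
                                 movie_duration, persistence_fraction,
                                 min_frames, pixel_size)
  assignments <- data.frame(
    patch_id = vapply(trajs, function(tr) as.integer(tr$id), integer(1)),
    cell_id = population$cell_of, class = cls)
  list(assignments = assignments,
       summary = summarize_cells(assignments, length(population$cells),
                                 condition))
}
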