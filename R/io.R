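# File formats and orchestration: multi-page TIFF stacks with JSON
# sidecars, trajectory/profile/summary CSVs, YAML run configuration and a
# reproducible end-to-end driver.
#
# TIFF storage contract: frames are written as 16-bit samples after an
# affine map of the stack's value range onto [0, 1]; the offset and scale
# are recorded in the sidecar so reading restores intensities to within
# 1/65535 of the dynamic range.

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' @param stack ny x nx x n_frames array, or a `rendered_movie` (its
#'   ground-truth tables are then written alongside as CSV).
#' @param path Output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param frame_interval Seconds per frame (taken from a `rendered_movie`
#'   automatically).
#' @param pixel_size Micrometers per pixel (optional metadata).
#' @return Invisibly, the sidecar metadata list.
#' @export
write_movie <- function(stack, path, frame_interval = NULL,
                        pixel_size = NULL) {
  truth <- NULL; truth_frames <- NULL
  if (inherits(stack, "rendered_movie")) {
    frame_interval <- frame_interval %||% stack$frame_interval
    pixel_size <- pixel_size %||% stack$pixel_size
    truth <- stack$truth; truth_frames <- stack$truth_frames
    stack <- stack$stack
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3,
            .is_num1(frame_interval), frame_interval > 0)
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(f) (stack[, , f] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, reduce = FALSE)
  meta <- list(frame_interval = frame_interval, pixel_size = pixel_size,
               n_frames = dim(stack)[3],
               image_size = dim(stack)[1:2],
               value_offset = lo, value_scale = scale,
               bits_per_sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    write.csv(truth, sub("\\.tiff?$", "_truth.csv", path),
              row.names = FALSE)
    write.csv(truth_frames, sub("\\.tiff?$", "_truth_frames.csv", path),
              row.names = FALSE)
  }
  invisible(meta)
}

#' Read a multi-page TIFF stack with timing metadata
#'
#' Reads the stack and restores intensities using the affine scale recorded
#' in the JSON sidecar (written by [write_movie()]). Timing comes from the
#' sidecar; without a sidecar, `frame_interval` must be supplied — missing
#' timing is an error, not a guess.
#'
#' @param path TIFF path.
#' @param frame_interval Seconds per frame; overrides/replaces sidecar
#'   timing.
#' @return List of class `patch_movie`: `stack` (ny x nx x n_frames),
#'   `frame_interval`, `pixel_size` (or NULL), `metadata`.
#' @export
read_movie <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) .stopf("cannot read movie: '%s' does not exist", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1)
    .stopf("inconsistent frame shapes in '%s'", path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  fi <- frame_interval %||% meta$frame_interval
  if (is.null(fi))
    .stopf("no frame interval: '%s' has no JSON sidecar and frame_interval was not supplied",
           path)
  offset <- meta$value_offset %||% 0
  scale <- meta$value_scale %||% 1
  stack <- array(0, dim = c(dims[[1]], length(frames)))
  for (f in seq_along(frames)) stack[, , f] <- frames[[f]] * scale + offset
  structure(list(stack = stack, frame_interval = fi,
                 pixel_size = meta$pixel_size, metadata = meta),
            class = "patch_movie")
}

#' Write / read trajectories as CSV
#'
#' Long format: one row per detection with columns `patch_id`, `frame`,
#' `x`, `y`, `intensity`.
#'
#' @param trajectories List of [patch_trajectory()] objects.
#' @param path CSV path.
#' @return `write_trajectories`: invisibly, the written data.frame.
#' @export
write_trajectories <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    cbind(patch_id = tr$id, tr$detections)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_trajectories
#' @param frame_interval Seconds per frame for the reconstructed
#'   trajectories.
#' @return `read_trajectories`: list of [patch_trajectory()] objects.
#' @export
read_trajectories <- function(path, frame_interval = 1) {
  df <- read.csv(path)
  stopifnot(all(c("patch_id", "frame", "x", "y", "intensity") %in% names(df)))
  lapply(split(df, df$patch_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    patch_trajectory(d[, c("frame", "x", "y", "intensity")],
                     id = d$patch_id[1], frame_interval = frame_interval)
  })
}

#' Write traces as CSV
#'
#' Long format: `patch_id`, `channel`, `frame`, `intensity`.
#'
#' @param pairs List of `trace_pair` objects or a `trace_ensemble`.
#' @param path CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_traces <- function(pairs, path) {
  if (inherits(pairs, "trace_ensemble")) pairs <- pairs$pairs
  rows <- lapply(pairs, function(p) {
    do.call(rbind, lapply(list(p$a, p$b), function(tr)
      data.frame(patch_id = tr$patch_id, channel = tr$channel,
                 frame = seq_along(tr$values) - 1L,
                 intensity = tr$values)))
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_traces
#' @param frame_interval Seconds per frame.
#' @return `read_traces`: list of `trace_pair` objects (two channels per
#'   patch).
#' @export
read_traces <- function(path, frame_interval = 1) {
  df <- read.csv(path)
  stopifnot(all(c("patch_id", "channel", "frame", "intensity") %in%
                  names(df)))
  lapply(split(df, df$patch_id), function(d) {
    chans <- unique(d$channel)
    if (length(chans) != 2)
      .stopf("patch %s: expected 2 channels, found %d", d$patch_id[1],
             length(chans))
    mk <- function(ch) {
      dd <- d[d$channel == ch, , drop = FALSE]
      dd <- dd[order(dd$frame), , drop = FALSE]
      fluorescence_trace(dd$intensity, frame_interval, ch,
                         patch_id = d$patch_id[1])
    }
    structure(list(a = mk(chans[1]), b = mk(chans[2]),
                   channel_lag = NA_real_), class = "trace_pair")
  })
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate -> profile / peaks / classify (and track, when a
#' movie is rendered) into one reproducible run. All outputs are CSV/JSON
#' under `out_dir`, together with a provenance record (`provenance.json`)
#' holding the full configuration, package version and seeds; identical
#' configuration yields byte-identical CSVs.
#'
#' @param config Named list or path to a YAML file with (all optional
#'   unless noted): `preset` (required), `seed` (default 1), `out_dir`
#'   (required), `n_events` (default 50), `simulate_movie` (default FALSE),
#'   `track` (list: `spot_radius`, `intensity_percentile`,
#'   `max_displacement`, `max_gap`, `min_frames`), `profile` (list:
#'   `reference_channel`, `max_lag`, `post_event_window`,
#'   `onset_fraction`), `classify` (list: `n_cells`, `class_probs`,
#'   `movie_duration`, `frame_interval`).
#' @return Invisibly, a list with the in-memory results (`ensemble`,
#'   `profiles`, `peaks`, `summary`, and `trajectories`/`movie` when
#'   tracking ran).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$preset)) .stopf("config$preset is required")
  if (is.null(config$out_dir)) .stopf("config$out_dir is required")
  seed <- config$seed %||% 1
  n_events <- config$n_events %||% 50
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  # --- simulate ---
  ens <- simulate_trace_ensemble(config$preset, n_events, seed = seed)
  write_traces(ens, file.path(out, "traces.csv"))
  write.csv(ens$truth, file.path(out, "traces_truth.csv"), row.names = FALSE)
  res$ensemble <- ens

  tset <- simulate_trajectories(config$preset, n_events, seed = seed + 1)
  write_trajectories(tset$trajectories, file.path(out, "trajectories.csv"))
  write.csv(tset$truth, file.path(out, "trajectories_truth.csv"),
            row.names = FALSE)

  if (isTRUE(config$simulate_movie)) {
    tk <- config$track %||% list()
    movie <- render_movie(scene_from_preset(config$preset,
                                            min(n_events, 36),
                                            seed = seed + 2))
    write_movie(movie, file.path(out, "movie.tif"))
    trk <- track_movie(movie,
                       spot_radius = tk$spot_radius %||% 3,
                       intensity_percentile = tk$intensity_percentile %||% 0.99,
                       max_displacement = tk$max_displacement %||% 3,
                       max_gap = tk$max_gap %||% 1,
                       min_frames = tk$min_frames %||% 3)
    write_trajectories(trk, file.path(out, "tracked.csv"))
    res$movie <- movie
    res$trajectories <- trk
  }

  # --- profile (TIRF pipeline) ---
  pr <- config$profile %||% list()
  profs <- run_tirf_pipeline(ens,
                             reference_channel = pr$reference_channel %||% "abp1",
                             config = pr)
  for (ch in names(profs$profiles)) {
    p <- profs$profiles[[ch]]
    write.csv(data.frame(time = p$time, median = p$median,
                         scaled_mad = p$scaled_mad),
              file.path(out, sprintf("profile_%s.csv", ch)),
              row.names = FALSE)
  }
  res$profiles <- profs

  # --- peaks ---
  pk <- peak_records(tset, strain = config$preset, experiment = "exp1")
  write.csv(pk, file.path(out, "peaks.csv"), row.names = FALSE)
  res$peaks <- pk

  # --- classify ---
  cl <- config$classify %||% list()
  pop <- simulate_cell_population(
    n_cells = cl$n_cells %||% 100,
    class_probs = unlist(cl$class_probs %||% c(0.8, 0.3, 0.5)),
    movie_duration = cl$movie_duration %||% 290,
    frame_interval = cl$frame_interval %||% 10,
    seed = seed + 3)
  cls <- classify_population(pop,
                             movie_duration = cl$movie_duration %||% 290,
                             condition = config$preset)
  write.csv(cls$assignments, file.path(out, "classes.csv"),
            row.names = FALSE)
  write.csv(cls$summary, file.path(out, "class_summary.csv"),
            row.names = FALSE)
  res$summary <- cls$summary

  provenance <- list(config = config, seed = seed,
                     package = "patchdyn",
                     version = as.character(packageVersion("patchdyn")),
                     onsets = as.list(profs$onsets))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
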