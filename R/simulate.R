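#' Single-patch fluorescence trace
#'
#' Container for one patch's intensity time series in one channel.
#'
#' @param values Numeric intensity vector (>= 3 samples).
#' @param frame_interval Sampling interval, seconds (> 0).
#' @param channel Channel label, e.g. `"egfp"` or `"abp1"`.
#' @param event_window Integer `c(start, end)` frame indices (0-based) of
#'   the true event, or `NULL` when unknown.
#' @param patch_id Identifier of the patch.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, frame_interval = 1, channel = "egfp",
                               event_window = NULL, patch_id = 1L) {
  stopifnot(is.numeric(values), .is_num1(frame_interval))
  if (length(values) < 3L) .stopf("a fluorescence trace needs >= 3 samples")
  if (frame_interval <= 0) .stopf("frame_interval must be > 0")
  if (!is.null(event_window)) {
    stopifnot(length(event_window) == 2L)
    if (event_window[1] < 0 || event_window[2] > length(values) - 1L)
      .stopf("event_window [%s, %s] outside trace of %d frames",
             event_window[1], event_window[2], length(values))
  }
  structure(list(values = as.numeric(values), frame_interval = frame_interval,
                 channel = channel, event_window = event_window,
                 patch_id = patch_id),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> patch %s, channel %s: %d frames @ %g s, range [%.3g, %.3g]\n",
              x$patch_id, x$channel, length(x$values), x$frame_interval,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a trace or profile
#' @param x A `fluorescence_trace`.
#' @return Numeric vector of frame times in seconds (frame 0 at t = 0).
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "fluorescence_trace"))
  (seq_along(x$values) - 1) * x$frame_interval
}

.event_frames <- function(kinetics, frame_interval, n_frames) {
  lo <- floor(kinetics$onset_time / frame_interval)
  hi <- ceiling((kinetics$onset_time + kinetics_lifetime(kinetics)) /
                  frame_interval)
  c(max(lo, 0L), min(hi, n_frames - 1L))
}

#' Simulate a two-channel trace pair for one patch
#'
#' Samples both channels' kinetic templates at the frame times and adds
#' Gaussian camera noise. The channel-b event is the channel-b template
#' delayed by `channel_lag` seconds, emulating the onset lag between an
#' endocytic protein and the Abp1 actin marker.
#'
#' @param kinetics_a,kinetics_b [patch_kinetics()] templates for the two
#'   channels (`kinetics_b` defaults to `kinetics_a`). `kinetics_b`'s onset
#'   is interpreted relative to channel a's time axis before the lag is
#'   applied.
#' @param channel_lag Onset delay of channel b relative to channel a,
#'   seconds (positive: b starts later).
#' @param frame_interval Sampling interval, seconds.
#' @param n_frames Number of frames; the movie must cover both events.
#' @param noise_sigma SD of additive Gaussian noise, intensity units.
#' @param seed Optional integer; when given, seeds the RNG (one global
#'   generator drives all draws).
#' @param channels Character vector of two channel labels.
#' @param patch_id Patch identifier propagated to both traces.
#' @return List of class `trace_pair`: elements `a` and `b`
#'   ([fluorescence_trace()] objects) plus `channel_lag` (the ground-truth
#'   lag in seconds).
#' @export
#' @examples
#' k <- patch_kinetics(20, 10, 2, 8, amplitude = 1, baseline = 0.1)
#' tp <- simulate_trace_pair(k, channel_lag = 10, n_frames = 80,
#'                           noise_sigma = 0, seed = 1)
#' tp$channel_lag  # 10
simulate_trace_pair <- function(kinetics_a, kinetics_b = kinetics_a,
                                channel_lag = 0, frame_interval = 1,
                                n_frames, noise_sigma = 0, seed = NULL,
                                channels = c("egfp", "abp1"), patch_id = 1L) {
  stopifnot(inherits(kinetics_a, "patch_kinetics"),
            inherits(kinetics_b, "patch_kinetics"),
            .is_num1(channel_lag), .is_count(n_frames), n_frames >= 3)
  if (!is.null(seed)) set.seed(seed)
  duration <- (n_frames - 1) * frame_interval
  kb <- kinetics_b
  kb$onset_time <- kb$onset_time + channel_lag
  end_a <- kinetics_a$onset_time + kinetics_lifetime(kinetics_a)
  end_b <- kb$onset_time + kinetics_lifetime(kb)
  if (kinetics_a$onset_time < 0 || kb$onset_time < 0 ||
      end_a > duration || end_b > duration)
    .stopf("event window [%.3g, %.3g] s exceeds movie duration %.3g s",
           min(kinetics_a$onset_time, kb$onset_time), max(end_a, end_b),
           duration)
  t <- (0:(n_frames - 1)) * frame_interval
  va <- kinetic_template(kinetics_a, t)
  vb <- kinetic_template(kb, t)
  if (noise_sigma > 0) {
    va <- va + rnorm(n_frames, 0, noise_sigma)
    vb <- vb + rnorm(n_frames, 0, noise_sigma)
  }
  structure(list(
    a = fluorescence_trace(va, frame_interval, channels[1],
                           .event_frames(kinetics_a, frame_interval, n_frames),
                           patch_id),
    b = fluorescence_trace(vb, frame_interval, channels[2],
                           .event_frames(kb, frame_interval, n_frames),
                           patch_id),
    channel_lag = channel_lag
  ), class = "trace_pair")
}

#' Simulate an ensemble of two-channel traces from a strain preset
#'
#' Draws `n_events` patches from a [patch_preset()]: per-event onset jitter
#' (uniform), per-event amplitude variability (normal, truncated at 5% of
#' the mean), fixed channel lag, and additive Gaussian noise in both
#' channels. This is the study design the TIRF profile pipeline assumes.
#'
#' @param preset A `patch_preset` or preset name.
#' @param n_events Number of patches.
#' @param seed Integer seed for the single RNG stream.
#' @param noise_sigma Override of the preset's noise SD (optional).
#' @return List of class `trace_ensemble`: `pairs` (list of `trace_pair`),
#'   `truth` (data.frame: patch_id, onset, amplitude_a, amplitude_b,
#'   channel_lag, lifetime), `preset` (name), `frame_interval`.
#' @export
simulate_trace_ensemble <- function(preset, n_events, seed = 1,
                                    noise_sigma = NULL) {
  if (is.character(preset)) preset <- patch_preset(preset)
  stopifnot(inherits(preset, "patch_preset"), .is_count(n_events),
            n_events >= 1)
  set.seed(seed)
  ns <- noise_sigma %||% preset$noise_sigma
  pairs <- vector("list", n_events)
  truth <- data.frame(patch_id = seq_len(n_events), onset = NA_real_,
                      amplitude_a = NA_real_, amplitude_b = NA_real_,
                      channel_lag = preset$channel_lag,
                      lifetime = preset$lifetime)
  for (i in seq_len(n_events)) {
    onset <- preset$onset_mean +
      runif(1, -preset$onset_jitter, preset$onset_jitter)
    amp_a <- max(rnorm(1, preset$amplitude, preset$amplitude_sd),
                 0.05 * preset$amplitude)
    amp_b <- max(rnorm(1, preset$reference$amplitude,
                       preset$reference$amplitude_sd),
                 0.05 * preset$reference$amplitude)
    ka <- patch_kinetics(onset, preset$assembly, preset$plateau,
                         preset$disassembly, amp_a, preset$baseline)
    kb <- patch_kinetics(onset, preset$reference$assembly,
                         preset$reference$plateau,
                         preset$reference$disassembly, amp_b,
                         preset$baseline)
    pairs[[i]] <- simulate_trace_pair(ka, kb, preset$channel_lag,
                                      preset$frame_interval, preset$n_frames,
                                      ns, seed = NULL, patch_id = i)
    truth$onset[i] <- onset
    truth$amplitude_a[i] <- amp_a
    truth$amplitude_b[i] <- amp_b
  }
  structure(list(pairs = pairs, truth = truth, preset = preset$name,
                 frame_interval = preset$frame_interval),
            class = "trace_ensemble")
}

#' Simulate tracked patch trajectories from a strain preset
#'
#' Produces per-frame centroid positions and intensities as the tracking
#' stage would report them, with known ground truth: intensity follows the
#' preset's kinetic template plus noise over the full observation window;
#' the centroid performs small lateral diffusion around its start position
#' and, for scission presets, ramps inward by
#' `preset$motion$inward_displacement` starting at the scission time.
#'
#' @param preset A `patch_preset` or preset name.
#' @param n_events Number of trajectories.
#' @param seed Integer seed.
#' @param noise_sigma Optional override of the preset's intensity noise SD.
#' @param field_size Side length of the (square) field patches are placed
#'   in, micrometers.
#' @return List of class `trajectory_set`: `trajectories` (list of
#'   `patch_trajectory`), `truth` (data.frame: patch_id, onset, amplitude,
#'   lifetime, scission_time — absolute seconds or NA), `frame_interval`.
#' @export
simulate_trajectories <- function(preset, n_events, seed = 1,
                                  noise_sigma = NULL, field_size = 20) {
  if (is.character(preset)) preset <- patch_preset(preset)
  stopifnot(inherits(preset, "patch_preset"), .is_count(n_events),
            n_events >= 1)
  set.seed(seed)
  ns <- noise_sigma %||% preset$noise_sigma
  dt <- preset$frame_interval
  nf <- preset$n_frames
  t <- (0:(nf - 1)) * dt
  mo <- preset$motion
  trajs <- vector("list", n_events)
  truth <- data.frame(patch_id = seq_len(n_events), onset = NA_real_,
                      amplitude = NA_real_, lifetime = preset$lifetime,
                      scission_time = NA_real_)
  for (i in seq_len(n_events)) {
    onset <- preset$onset_mean +
      runif(1, -preset$onset_jitter, preset$onset_jitter)
    amp <- max(rnorm(1, preset$amplitude, preset$amplitude_sd),
               0.05 * preset$amplitude)
    k <- patch_kinetics(onset, preset$assembly, preset$plateau,
                        preset$disassembly, amp, preset$baseline)
    intens <- kinetic_template(k, t)
    if (ns > 0) intens <- intens + rnorm(nf, 0, ns)
    x0 <- runif(1, 1, field_size - 1)
    y0 <- runif(1, 1, field_size - 1)
    x <- x0 + cumsum(rnorm(nf, 0, mo$lateral_sigma))
    y <- y0 + cumsum(rnorm(nf, 0, mo$lateral_sigma))
    sci <- NA_real_
    if (is.finite(mo$scission_offset)) {
      sci <- onset + mo$scission_offset
      # inward ramp along a fixed direction, 0 -> inward_displacement over
      # inward_duration seconds
      th <- runif(1, 0, 2 * pi)
      ramp <- pmin(pmax((t - sci) / mo$inward_duration, 0), 1) *
        mo$inward_displacement
      x <- x + cos(th) * ramp
      y <- y + sin(th) * ramp
    }
    trajs[[i]] <- patch_trajectory(
      data.frame(frame = 0:(nf - 1), x = x, y = y, intensity = intens),
      id = i, frame_interval = dt)
    truth$onset[i] <- onset
    truth$amplitude[i] <- amp
    truth$scission_time[i] <- sci
  }
  structure(list(trajectories = trajs, truth = truth, frame_interval = dt,
                 preset = preset$name),
            class = "trajectory_set")
}
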