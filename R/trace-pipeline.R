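# TIRF trace analysis: integral normalization, cross-correlation alignment,
# robust median profiles, derivative-based background, 0-1 rescaling.

.simpson <- function(values, dt) {
  n <- length(values)
  if (n < 3) .stopf("Simpson integration needs >= 3 samples, got %d", n)
  nint <- n - 1L
  if (nint %% 2L == 0L) {
    # even interval count: pure composite Simpson
    i4 <- seq(2, n - 1, by = 2)
    i2 <- if (n >= 5) seq(3, n - 2, by = 2) else integer(0)
    dt / 3 * (values[1] + values[n] + 4 * sum(values[i4]) +
                2 * sum(values[i2]))
  } else {
    # odd interval count: Simpson on the first n-2 intervals (even count),
    # trapezoid on the last
    .simpson(values[seq_len(n - 1L)], dt) +
      dt * (values[n - 1L] + values[n]) / 2
  }
}

#' Composite Simpson integral of a uniformly sampled trace
#'
#' Composite Simpson's rule over the uniform frame grid. For an odd number
#' of intervals (even sample count) the last interval is integrated with
#' the trapezoidal rule and Simpson's rule covers the rest. Exact for
#' quadratics (and for cubics when the interval count is even).
#'
#' @param x A [fluorescence_trace()] or numeric vector (>= 3 samples).
#' @param frame_interval Sampling interval in seconds (taken from the trace
#'   when `x` is a `fluorescence_trace`).
#' @return Integral in units * seconds.
#' @export
#' @examples
#' simpson_integral(rep(2, 11), frame_interval = 1)       # 2 * 10 = 20
#' t <- seq(0, 2, by = 0.1)
#' simpson_integral(t^2, frame_interval = 0.1)            # 8/3 exactly
simpson_integral <- function(x, frame_interval = NULL) {
  if (inherits(x, "fluorescence_trace")) {
    frame_interval <- x$frame_interval
    x <- x$values
  }
  stopifnot(is.numeric(x), .is_num1(frame_interval), frame_interval > 0)
  .simpson(as.numeric(x), frame_interval)
}

#' Normalize a trace by its Simpson integral
#'
#' Divides the intensity values by the trace's time integral so that the
#' normalized trace integrates to 1. Removes patch-to-patch brightness
#' differences before ensemble averaging.
#'
#' @param trace A [fluorescence_trace()].
#' @return The trace with normalized values.
#' @export
integral_normalize <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  I <- simpson_integral(trace)
  if (!is.finite(I) || I <= 0)
    .stopf("trace integral is %.3g; integral normalization needs a positive integral (patch %s, channel %s)",
           I, trace$patch_id, trace$channel)
  trace$values <- trace$values / I
  trace
}

#' Consistency-scaled median absolute deviation
#'
#' `median(|x - median(x)|) * 1.4826`; the scaling makes the MAD an
#' asymptotically unbiased estimator of the standard deviation for
#' normally distributed data.
#'
#' @param values Numeric vector (>= 1 value).
#' @return Scalar scaled MAD (0 for constant input).
#' @export
#' @examples
#' scaled_mad(1:5)  # 1.4826
scaled_mad <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  median(abs(values - median(values))) * MAD_CONSISTENCY
}

#' Integer lag maximizing the cross-correlation of two signals
#'
#' Brute-force search over lags `-max_lag..max_lag` of the zero-mean
#' cross-correlation; a positive lag means `signal_b` lags (starts after)
#' `signal_a`. Ties are broken towards the smallest |lag|, then the
#' smallest lag.
#'
#' @param signal_a,signal_b Numeric vectors (or `fluorescence_trace`s) on
#'   the same sampling grid.
#' @param max_lag Maximum |lag| searched, frames (< signal length).
#' @return Integer lag in frames.
#' @export
crosscorr_lag <- function(signal_a, signal_b, max_lag = 20) {
  if (inherits(signal_a, "fluorescence_trace")) signal_a <- signal_a$values
  if (inherits(signal_b, "fluorescence_trace")) signal_b <- signal_b$values
  stopifnot(is.numeric(signal_a), is.numeric(signal_b),
            length(signal_a) == length(signal_b), .is_count(max_lag))
  n <- length(signal_a)
  if (max_lag >= n) .stopf("max_lag (%d) must be smaller than the signal length (%d)",
                           max_lag, n)
  a <- signal_a - mean(signal_a)
  b <- signal_b - mean(signal_b)
  if (all(a == 0) || all(b == 0))
    .stopf("cross-correlation undefined for a constant signal")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[seq_len(n - k)] * b[seq_len(n - k) + k])
    else sum(a[seq_len(n + k) - k] * b[seq_len(n + k)])
  }, numeric(1))
  best <- which(cc == max(cc))
  best <- best[order(abs(lags[best]), lags[best])][1]
  as.integer(lags[best])
}

# shift a value vector left by `lag` frames (positive lag advances the
# signal, i.e. undoes a delay), padding with the edge value
.shift_values <- function(v, lag) {
  n <- length(v)
  if (lag == 0) return(v)
  if (lag > 0) c(v[(lag + 1):n], rep(v[n], lag))
  else c(rep(v[1], -lag), v[seq_len(n + lag)])
}

#' Align a two-channel ensemble by cross-correlating the reference channel
#'
#' Computes one integer-frame lag per patch by cross-correlating its
#' reference-channel trace against an iteratively updated ensemble
#' template (initialized with the first patch's reference trace, running
#' mean of aligned traces thereafter), then shifts both channels of the
#' patch by that lag.
#'
#' @param pairs List of `trace_pair` objects (see [simulate_trace_pair()])
#'   or a `trace_ensemble`.
#' @param reference_channel Label of the reference channel (default
#'   `"abp1"`).
#' @param max_lag Maximum |lag| searched, frames.
#' @return List of class `aligned_ensemble`: `pairs` (shifted), `lags`
#'   (integer vector, one per patch), `reference_channel`.
#' @export
align_ensemble <- function(pairs, reference_channel = "abp1", max_lag = 20) {
  if (inherits(pairs, "trace_ensemble")) pairs <- pairs$pairs
  stopifnot(is.list(pairs), length(pairs) >= 1)
  get_ref <- function(pair) {
    for (nm in c("a", "b")) {
      tr <- pair[[nm]]
      if (inherits(tr, "fluorescence_trace") &&
          identical(tr$channel, reference_channel)) return(nm)
    }
    .stopf("patch %s has no trace in reference channel '%s'",
           pair$a$patch_id %||% "?", reference_channel)
  }
  lags <- integer(length(pairs))
  template <- NULL
  n_in_template <- 0
  out <- pairs
  for (i in seq_along(pairs)) {
    ref_nm <- get_ref(pairs[[i]])
    ref <- pairs[[i]][[ref_nm]]$values
    lag <- if (is.null(template)) 0L else
      crosscorr_lag(template, ref, max_lag)
    lags[i] <- lag
    shifted <- pairs[[i]]
    for (nm in c("a", "b"))
      shifted[[nm]]$values <- .shift_values(shifted[[nm]]$values, lag)
    out[[i]] <- shifted
    ref_al <- shifted[[ref_nm]]$values
    template <- if (is.null(template)) ref_al else
      (template * n_in_template + ref_al) / (n_in_template + 1)
    n_in_template <- n_in_template + 1
  }
  structure(list(pairs = out, lags = lags,
                 reference_channel = reference_channel),
            class = "aligned_ensemble")
}

#' Median +/- scaled-MAD profile of an ensemble of traces
#'
#' Per-timepoint median and consistency-scaled MAD across traces of one
#' channel.
#'
#' @param traces List of [fluorescence_trace()]s on a common grid, or an
#'   `aligned_ensemble` together with `channel`.
#' @param channel When `traces` is an `aligned_ensemble`: which channel to
#'   profile.
#' @return Object of class `median_profile`: data.frame with columns
#'   `time`, `median`, `scaled_mad`; attributes `frame_interval`,
#'   `normalized` (FALSE), `background` and `peak` (NA until rescaled).
#' @export
median_profile <- function(traces, channel = NULL) {
  if (inherits(traces, "aligned_ensemble")) {
    stopifnot(!is.null(channel))
    traces <- lapply(traces$pairs, function(p) {
      nm <- if (identical(p$a$channel, channel)) "a"
            else if (identical(p$b$channel, channel)) "b"
            else .stopf("no trace in channel '%s'", channel)
      p[[nm]]
    })
  }
  stopifnot(is.list(traces), length(traces) >= 1)
  for (tr in traces) stopifnot(inherits(tr, "fluorescence_trace"))
  n <- unique(vapply(traces, function(tr) length(tr$values), integer(1)))
  if (length(n) != 1)
    .stopf("all traces must have the same length for profiling")
  dt <- traces[[1]]$frame_interval
  m <- vapply(traces, `[[`, numeric(n), "values")
  out <- data.frame(time = (0:(n - 1)) * dt,
                    median = apply(m, 1, median),
                    scaled_mad = apply(m, 1, scaled_mad))
  class(out) <- c("median_profile", "data.frame")
  attr(out, "frame_interval") <- dt
  attr(out, "normalized") <- FALSE
  attr(out, "background") <- NA_real_
  attr(out, "peak") <- NA_real_
  out
}

#' @export
plot.median_profile <- function(x, ...) {
  plot(x$time, x$median, type = "n", xlab = "time (s)",
       ylab = if (isTRUE(attr(x, "normalized"))) "intensity (norm.)"
              else "intensity (AU)", ...)
  polygon(c(x$time, rev(x$time)),
          c(x$median - x$scaled_mad, rev(x$median + x$scaled_mad)),
          col = rgb(0.2, 0.5, 0.3, 0.3), border = NA)
  lines(x$time, x$median, lwd = 2, col = "darkgreen")
  invisible(x)
}

# Savitzky-Golay first-derivative convolution coefficients for a symmetric
# window, via the local least-squares pseudoinverse. For polynomial order 2
# (or 3) and window n they reduce to j / sum(j^2), j = -(n-1)/2 .. (n-1)/2.
.sg_deriv_coef <- function(n = 11, order = 2) {
  m <- (n - 1) %/% 2
  j <- -m:m
  A <- outer(j, 0:order, `^`)
  # row of (A^T A)^-1 A^T selecting the first-derivative coefficient
  (solve(crossprod(A), t(A)))[2, ]
}

#' Savitzky-Golay first derivative of a sampled signal
#'
#' Convolution with the 11-point, polynomial-order-2 Savitzky-Golay
#' first-derivative kernel, scaled by `1/frame_interval`; edges are handled
#' by mirror padding. Exact (to rounding) on constant, linear and quadratic
#' signals at interior points.
#'
#' @param signal Numeric vector (length >= 11) or `fluorescence_trace`.
#' @param frame_interval Sampling interval, seconds.
#' @param window Odd window length (default 11).
#' @return Numeric derivative array, same length as `signal`.
#' @export
sg_first_derivative <- function(signal, frame_interval = 1, window = 11) {
  if (inherits(signal, "fluorescence_trace")) {
    frame_interval <- signal$frame_interval
    signal <- signal$values
  }
  stopifnot(is.numeric(signal), .is_num1(frame_interval), frame_interval > 0,
            .is_count(window), window %% 2 == 1)
  n <- length(signal)
  if (n < window)
    .stopf("Savitzky-Golay derivative needs >= %d samples, got %d", window, n)
  m <- (window - 1) %/% 2
  coef <- .sg_deriv_coef(window, order = 2)
  padded <- c(signal[(m + 1):2], signal, signal[(n - 1):(n - m)])
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- sum(coef * padded[i:(i + window - 1)])
  out / frame_interval
}

#' Estimate the post-event background of a median profile
#'
#' Locates local extrema of the median signal inside the post-event window
#' as sign changes of its Savitzky-Golay first derivative, and returns the
#' mean of the median values at those extrema. With no extrema in the
#' window, falls back to the window mean.
#'
#' @param profile A [median_profile()].
#' @param post_event_window Integer `c(start, end)` frame indices
#'   (0-based, inclusive) after the endocytic event.
#' @return Scalar background level, intensity units.
#' @export
estimate_background <- function(profile, post_event_window) {
  stopifnot(inherits(profile, "median_profile"),
            length(post_event_window) == 2)
  n <- nrow(profile)
  w0 <- post_event_window[1]; w1 <- post_event_window[2]
  if (w0 < 0 || w1 > n - 1 || w0 > w1)
    .stopf("post_event_window [%s, %s] outside profile of %d frames",
           w0, w1, n)
  d <- sg_first_derivative(profile$median, attr(profile, "frame_interval"))
  idx <- (w0 + 1):(w1 + 1)  # 1-based
  ext <- integer(0)
  for (i in idx) {
    if (i >= n) break
    if (d[i] == 0 && i > 1) ext <- c(ext, i)
    else if (d[i] * d[i + 1] < 0)
      ext <- c(ext, if (abs(d[i]) <= abs(d[i + 1])) i else i + 1)
  }
  ext <- unique(ext[ext %in% idx])
  if (length(ext) == 0) mean(profile$median[idx])
  else mean(profile$median[ext])
}

#' Rescale a median profile to [0, 1] with error propagation
#'
#' Linear map sending the background level to 0 and the profile maximum to
#' 1; the scaled MAD is divided by the same factor (`max - background`).
#'
#' @param profile A [median_profile()].
#' @param background Background level (e.g. from [estimate_background()]).
#' @return The normalized `median_profile` (attributes `normalized = TRUE`,
#'   `background`, `peak` record the mapping).
#' @export
rescale_01 <- function(profile, background) {
  stopifnot(inherits(profile, "median_profile"), .is_num1(background))
  peak <- max(profile$median)
  if (peak <= background)
    .stopf("profile maximum (%.3g) does not exceed background (%.3g); no event above background",
           peak, background)
  span <- peak - background
  out <- profile
  out$median <- (profile$median - background) / span
  out$scaled_mad <- profile$scaled_mad / span
  attr(out, "normalized") <- TRUE
  attr(out, "background") <- background
  attr(out, "peak") <- peak
  out
}

#' Onset time of a normalized profile
#'
#' Operational onset: the first upward crossing of `fraction` of the
#' normalized peak (linearly interpolated), searching from the start up to
#' the peak.
#'
#' @param profile A normalized [median_profile()] (peak 1, background 0).
#' @param fraction Crossing level as a fraction of the peak (default 0.1).
#' @return Onset time in seconds.
#' @export
profile_onset <- function(profile, fraction = 0.1) {
  stopifnot(inherits(profile, "median_profile"))
  if (!isTRUE(attr(profile, "normalized")))
    .stopf("profile_onset expects a normalized profile; call rescale_01() first")
  v <- profile$median
  pk <- which.max(v)
  i <- which(v[seq_len(pk)] >= fraction)[1]
  if (is.na(i)) .stopf("profile never reaches %.3g of its peak", fraction)
  if (i == 1) return(profile$time[1])
  # linear interpolation between i-1 and i
  t0 <- profile$time[i - 1]; t1 <- profile$time[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (fraction - v0) / (v1 - v0) * (t1 - t0)
}

#' Full TIRF median-profile pipeline
#'
#' Executes, per channel, the four analysis steps applied to two-channel
#' TIRF traces: (1) normalize every trace by its Simpson integral;
#' (2) time-align patches by cross-correlating the reference channel;
#' (3) per-timepoint median and consistency-scaled MAD; (4) estimate the
#' post-event background from Savitzky-Golay-derivative extrema and
#' rescale to [0, 1] with error propagation.
#'
#' @param pairs List of `trace_pair` objects or a `trace_ensemble`
#'   (>= 3 patches).
#' @param reference_channel Reference channel label (default `"abp1"`).
#' @param config Optional list: `max_lag` (frames, default 20),
#'   `post_event_window` (`c(start, end)` 0-based frames; default the last
#'   third of the trace), `onset_fraction` (default 0.1).
#' @return List of class `tirf_profiles`: `profiles` (named list of
#'   normalized [median_profile()]s, one per channel), `lags`, `onsets`
#'   (named numeric, seconds), `params` (provenance of all parameters).
#' @export
run_tirf_pipeline <- function(pairs, reference_channel = "abp1",
                              config = list()) {
  if (inherits(pairs, "trace_ensemble")) pairs <- pairs$pairs
  stopifnot(is.list(pairs))
  if (length(pairs) < 3)
    .stopf("TIRF pipeline needs >= 3 patches, got %d", length(pairs))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s': %s", name, conditionMessage(e)))
  }
  max_lag <- config$max_lag %||% 20
  n <- length(pairs[[1]]$a$values)
  post_w <- config$post_event_window %||% c(floor(2 * n / 3), n - 1)
  onset_fraction <- config$onset_fraction %||% 0.1

  norm <- stage("normalize", lapply(pairs, function(p) {
    p$a <- integral_normalize(p$a)
    p$b <- integral_normalize(p$b)
    p
  }))
  aligned <- stage("align", align_ensemble(norm, reference_channel, max_lag))
  channels <- unique(c(pairs[[1]]$a$channel, pairs[[1]]$b$channel))
  profiles <- list()
  onsets <- numeric(0)
  for (ch in channels) {
    prof <- stage("profile", median_profile(aligned, channel = ch))
    bg <- stage("background", estimate_background(prof, post_w))
    prof <- stage("rescale", rescale_01(prof, bg))
    profiles[[ch]] <- prof
    onsets[ch] <- profile_onset(prof, onset_fraction)
  }
  structure(list(profiles = profiles, lags = aligned$lags, onsets = onsets,
                 params = list(reference_channel = reference_channel,
                               max_lag = max_lag,
                               post_event_window = post_w,
                               onset_fraction = onset_fraction,
                               n_patches = length(pairs))),
            class = "tirf_profiles")
}

#' @export
print.tirf_profiles <- function(x, ...) {
  cat(sprintf("<tirf_profiles> %d patches, channels: %s\n",
              x$params$n_patches, paste(names(x$profiles), collapse = ", ")))
  for (ch in names(x$onsets))
    cat(sprintf("  %s: onset (%.0f%% of peak) at %.2f s\n", ch,
                100 * x$params$onset_fraction, x$onsets[ch]))
  invisible(x)
}
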