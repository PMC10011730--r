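#' Kinetic template of a single endocytic patch event
#'
#' Describes one patch's fluorescence time course as a piecewise-linear
#' event on top of a constant baseline: a linear (optionally exponential)
#' assembly ramp of duration `assembly_duration`, an optional plateau at
#' `amplitude`, and a linear disassembly back to baseline. The patch
#' lifetime is the sum of the three durations.
#'
#' @param onset_time Event start, seconds from movie start.
#' @param assembly_duration,plateau_duration,disassembly_duration Segment
#'   durations in seconds, each `>= 0`.
#' @param amplitude Event peak height above baseline, arbitrary fluorescence
#'   units, `> 0`.
#' @param baseline Constant background level added everywhere (default 0).
#' @param exponential_assembly If `TRUE` the assembly ramp is a saturating
#'   exponential reaching `amplitude` at the end of the assembly phase
#'   instead of a straight line.
#' @return An object of class `patch_kinetics`.
#' @seealso [kinetic_template()], [template_integral()], [simulate_trace_pair()]
#' @export
#' @examples
#' k <- patch_kinetics(onset_time = 20, assembly_duration = 10,
#'                     plateau_duration = 2, disassembly_duration = 8,
#'                     amplitude = 1)
#' kinetics_lifetime(k)  # 20 s
patch_kinetics <- function(onset_time, assembly_duration, plateau_duration = 0,
                           disassembly_duration, amplitude, baseline = 0,
                           exponential_assembly = FALSE) {
  stopifnot(.is_num1(onset_time), .is_num1(assembly_duration),
            .is_num1(plateau_duration), .is_num1(disassembly_duration),
            .is_num1(amplitude), .is_num1(baseline))
  if (assembly_duration < 0 || plateau_duration < 0 || disassembly_duration < 0)
    .stopf("all durations must be >= 0")
  if (amplitude <= 0) .stopf("amplitude must be > 0")
  structure(list(onset_time = onset_time,
                 assembly_duration = assembly_duration,
                 plateau_duration = plateau_duration,
                 disassembly_duration = disassembly_duration,
                 amplitude = amplitude,
                 baseline = baseline,
                 exponential_assembly = isTRUE(exponential_assembly)),
            class = "patch_kinetics")
}

#' @export
print.patch_kinetics <- function(x, ...) {
  cat(sprintf(
    "<patch_kinetics> onset %.3g s | assembly %.3g + plateau %.3g + disassembly %.3g s (lifetime %.3g s) | amplitude %.3g + baseline %.3g\n",
    x$onset_time, x$assembly_duration, x$plateau_duration,
    x$disassembly_duration, kinetics_lifetime(x), x$amplitude, x$baseline))
  invisible(x)
}

#' Patch lifetime implied by a kinetic template
#'
#' @param kinetics A [patch_kinetics()] object.
#' @return Lifetime in seconds (assembly + plateau + disassembly).
#' @export
kinetics_lifetime <- function(kinetics) {
  stopifnot(inherits(kinetics, "patch_kinetics"))
  kinetics$assembly_duration + kinetics$plateau_duration +
    kinetics$disassembly_duration
}

#' Evaluate a kinetic template at given times
#'
#' Noise-free fluorescence of the event at arbitrary time points. The value
#' is `baseline` outside the event window.
#'
#' @param kinetics A [patch_kinetics()] object.
#' @param t Numeric vector of times, seconds.
#' @return Numeric vector of intensities, same length as `t`.
#' @export
kinetic_template <- function(kinetics, t) {
  k <- kinetics
  stopifnot(inherits(k, "patch_kinetics"), is.numeric(t))
  tt <- t - k$onset_time
  asm <- k$assembly_duration; pl <- k$plateau_duration
  dis <- k$disassembly_duration
  v <- numeric(length(t))
  if (asm > 0) {
    i <- tt > 0 & tt <= asm
    v[i] <- if (k$exponential_assembly)
      k$amplitude * expm1(3 * tt[i] / asm) / expm1(3)
    else
      k$amplitude * tt[i] / asm
  }
  i <- tt > asm & tt <= asm + pl
  v[i] <- k$amplitude
  if (dis > 0) {
    i <- tt > asm + pl & tt < asm + pl + dis
    v[i] <- k$amplitude * (1 - (tt[i] - asm - pl) / dis)
  }
  v + k$baseline
}

#' Closed-form integral of a kinetic template
#'
#' Analytic time integral of the template over `[0, duration]`, assuming the
#' whole event lies inside that window. Used as the ground-truth check for
#' numerical (Simpson) integration of sampled traces.
#'
#' @param kinetics A [patch_kinetics()] object.
#' @param duration Total integration window, seconds.
#' @return Integral in units * seconds.
#' @export
template_integral <- function(kinetics, duration) {
  k <- kinetics
  stopifnot(inherits(k, "patch_kinetics"), .is_num1(duration), duration > 0)
  asm <- k$assembly_duration
  event <- if (k$exponential_assembly)
    k$amplitude * (asm * (expm1(3) / 3 - 1) / expm1(3) +
                     k$plateau_duration + k$disassembly_duration / 2)
  else
    k$amplitude * (asm / 2 + k$plateau_duration + k$disassembly_duration / 2)
  k$baseline * duration + event
}
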