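# Strain presets.
#
# Each preset encodes the published kinetics of one endogenously tagged
# endocytic protein (eGFP channel) imaged together with the actin marker
# Abp1-mCherry (reference channel): mean peak amplitude with its
# event-to-event SD (arbitrary units, on the scale where the brightest
# wild-type strain of a dataset is ~1), patch lifetime split into
# assembly / plateau / disassembly, the onset lag of the Abp1 reference
# channel, and, for the scission marker Rvs167, the scission time (seconds
# after patch onset) and the inward centroid jump that accompanies it.
#
# Splits of a lifetime into segments are not published; they are fixed here
# once (roughly half assembly, short plateau, the rest disassembly) and act
# as the generator's ground truth.

.preset_table <- list(
  "WT-Bzz1" = list(amplitude = 0.99, amplitude_sd = 0.10, assembly = 10,
                   plateau = 2, disassembly = 8, channel_lag = 10),
  "Bzz1-SH3BD" = list(amplitude = 0.71, amplitude_sd = 0.15, assembly = 10,
                      plateau = 2, disassembly = 8, channel_lag = 10),
  "Bzz1-PRMDSH3BD" = list(amplitude = 0.62, amplitude_sd = 0.16, assembly = 10,
                          plateau = 2, disassembly = 8, channel_lag = 10),
  "Bzz1-SH3A*" = list(amplitude = 0.89, amplitude_sd = 0.26, assembly = 10,
                      plateau = 2, disassembly = 8, channel_lag = 10),
  "Bzz1-PRM*" = list(amplitude = 0.90, amplitude_sd = 0.11, assembly = 10,
                     plateau = 2, disassembly = 8, channel_lag = 10),
  "Las17-WT" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 15,
                    plateau = 5, disassembly = 10, channel_lag = 10),
  "Las17-abp1SH3D" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 19,
                          plateau = 6, disassembly = 13, channel_lag = 10),
  "Vrp1-WT" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 10,
                   plateau = 2, disassembly = 8, channel_lag = 10),
  "Vrp1-abp1SH3D" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 14,
                         plateau = 3, disassembly = 11, channel_lag = 10),
  "Myo5" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 5,
                plateau = 1, disassembly = 4, channel_lag = 5),
  "Aim21" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 5,
                 plateau = 1, disassembly = 4, channel_lag = 5),
  "Rvs167-WT" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 5,
                     plateau = 0, disassembly = 3, channel_lag = 2,
                     scission_offset = 5),
  "Rvs167-abp1SH3D" = list(amplitude = 1.0, amplitude_sd = 0.10, assembly = 8,
                           plateau = 0, disassembly = 3, channel_lag = 2,
                           scission_offset = 8)
)

#' Names of available strain presets
#'
#' @return Character vector of preset names accepted by [patch_preset()].
#' @export
preset_names <- function() names(.preset_table)

#' Ground-truth parameter set for a published strain
#'
#' Returns the fully specified generator parameters for one imaging
#' condition: kinetics of the tagged protein (channel `"egfp"`), kinetics of
#' the Abp1-mCherry reference (channel `"abp1"`), the onset lag between the
#' two channels, per-event variability, motion parameters, and acquisition
#' defaults (1 s frame interval for TIRF-style traces).
#'
#' Amplitudes are on the scale where the brightest strain of a dataset is
#' ~1 AU; lifetimes are the published ~20 s (Bzz1 variants, Vrp1), ~30 s
#' (Las17), ~10 s (Myo5/Aim21) values, with the `abp1SH3D` background adding
#' the published lifetime extensions. `Rvs167-*` presets additionally carry
#' `scission_offset` (seconds after onset at which the centroid jumps
#' inward while the intensity collapses), 3 s later in the mutant.
#'
#' @param name Preset name; see [preset_names()].
#' @return An object of class `patch_preset`: a list with elements
#'   `name`, `amplitude`, `amplitude_sd`, `assembly`, `plateau`,
#'   `disassembly`, `lifetime`, `channel_lag`, `baseline`, `noise_sigma`,
#'   `frame_interval`, `n_frames`, `onset_mean`, `onset_jitter`,
#'   `reference` (Abp1 kinetics parameters), `motion` (lateral diffusion,
#'   inward displacement, scission offset or `NA`).
#' @export
#' @examples
#' p <- patch_preset("WT-Bzz1")
#' p$lifetime     # 20
#' p$channel_lag  # 10
patch_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.preset_table))
    .stopf("unknown preset '%s'; available presets: %s",
           as.character(name)[1], paste(preset_names(), collapse = ", "))
  p <- .preset_table[[name]]
  lifetime <- p$assembly + p$plateau + p$disassembly
  onset_mean <- 25
  onset_jitter <- 5
  # reference (Abp1) event starts channel_lag after the tagged protein and
  # ends with it; its own assembly keeps the two 10%-onsets channel_lag apart
  ref_life <- max(lifetime - p$channel_lag, 4)
  ref_dis <- min(2, ref_life / 4)
  structure(list(
    name = name,
    amplitude = p$amplitude, amplitude_sd = p$amplitude_sd,
    assembly = p$assembly, plateau = p$plateau, disassembly = p$disassembly,
    lifetime = lifetime,
    channel_lag = p$channel_lag,
    baseline = 0.1,
    noise_sigma = 0.05,
    frame_interval = 1,
    n_frames = ceiling(onset_mean + onset_jitter + lifetime +
                         p$channel_lag + 35),
    onset_mean = onset_mean, onset_jitter = onset_jitter,
    reference = list(amplitude = 1.0, amplitude_sd = 0.10,
                     assembly = ref_life - ref_dis, plateau = 0,
                     disassembly = ref_dis),
    motion = list(lateral_sigma = 0.01,
                  inward_displacement = 0.2,
                  inward_duration = 2,
                  scission_offset = p$scission_offset %||% NA_real_)
  ), class = "patch_preset")
}

#' @export
print.patch_preset <- function(x, ...) {
  cat(sprintf("<patch_preset> %s: lifetime %g s (%g/%g/%g), amplitude %.2f +/- %.2f AU, Abp1 lag %g s%s\n",
              x$name, x$lifetime, x$assembly, x$plateau, x$disassembly,
              x$amplitude, x$amplitude_sd, x$channel_lag,
              if (is.finite(x$motion$scission_offset))
                sprintf(", scission at onset + %g s", x$motion$scission_offset)
              else ""))
  invisible(x)
}
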