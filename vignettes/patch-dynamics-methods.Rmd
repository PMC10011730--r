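---
title: "Quantifying endocytic patch dynamics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endocytic patch dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchdyn)
```

## The measurement problem

Clathrin-mediated endocytosis in budding yeast proceeds through stereotyped
"patches": diffraction-limited fluorescent spots at the plasma membrane in
which coat proteins, nucleation-promoting factors, actin and scission
machinery assemble and disassemble over tens of seconds. Live-cell
two-channel imaging of such patches (a tagged protein of interest plus the
actin marker Abp1 as a time reference) produces two kinds of raw data:

* **TIRF trace tables** — per-patch fluorescence intensity time series in
  both channels, sampled at around 1 s, from manually or automatically
  selected patches; and
* **Epifluorescence / time-lapse movies** — image stacks (typically 10 s
  frame rate over ~5 min for patch classification) from which patches must
  be detected, tracked, measured and classified.

`patchdyn` implements the full quantification chain for both, plus a
synthetic generator that renders two-channel events with known kinetics so
that every estimator can be validated against ground truth.

## The event model

A single patch event is modelled as a piecewise-linear pulse on a constant
baseline (`patch_kinetics()`): a linear assembly ramp of duration
$a$ reaching amplitude $A$, an optional plateau of duration $p$, and a
linear disassembly of duration $d$; lifetime $L = a + p + d$. An optional
saturating-exponential assembly is available for assembly curves that are
"slightly exponential", but the linear ramp is the default as the simplest
shape consistent with the observed assembly curves. The second channel is
the same model delayed by a channel lag $\ell$; in the wild-type
configuration Abp1 starts ~10 s after the tagged protein and the two
signals end together.

Strain presets (`patch_preset()`) pin the generator to the published
operating points: peak amplitudes 0.99/0.71/0.62/0.89/0.90 AU for the Bzz1
variants (with per-event SDs 0.10/0.15/0.16/0.26/0.11), lifetimes ~20 s
(Bzz1 variants, Vrp1-WT), ~30 s (Las17-WT), ~10 s (Myo5, Aim21), the +8 s
lifetime extension of Las17/Vrp1 in the `abp1SH3D` background, and for the
scission marker Rvs167 a ~5 s assembly followed by an intensity collapse
with a simultaneous 0.2 µm inward centroid jump, delayed by 3 s in the
mutant. The split of each published lifetime into assembly/plateau/
disassembly is not published; it is fixed once per preset (roughly
50/10/40) and is part of the generator's ground truth, not a tuning knob.

Defaults chosen for unpublished acquisition parameters: 1 s frame interval
for TIRF-style traces, 10 s for classification movies (4 min 50 s
duration); onset base 25 s with ±5 s uniform jitter so that alignment is
actually exercised; baseline 0.1 AU; additive Gaussian camera noise with
SD 0.05 AU on traces and 0.01 on rendered pixels (read-noise proxy; shot
noise is out of scope); pixel size 0.1 µm; PSF sigma 0.15 µm; lateral
centroid diffusion 0.01 µm per frame. Rendered spots use an
amplitude-parameterized isotropic Gaussian (peak pixel equals the template
intensity). All stochastic draws flow through one seeded RNG stream per
generator call, so identical seeds give bit-identical scenes.

## The TIRF profile pipeline

`run_tirf_pipeline()` executes the four trace-analysis steps in order, per
channel:

1. **Integral normalization.** Each trace is divided by its composite
   Simpson integral, removing patch-to-patch brightness differences. For an
   odd interval count the final interval uses the trapezoidal rule
   (alternative composite rules differ below test tolerance; the pure
   Simpson branch is exact for cubics).
2. **Alignment.** One integer-frame lag per patch is found by maximizing
   the zero-mean cross-correlation of its reference (Abp1) trace against an
   ensemble template; both channels of the patch are shifted by that lag.
   The template is initialized with the first patch's reference trace and
   updated as a running mean of aligned traces — a documented,
   deterministic choice; the pipeline output is therefore invariant to the
   order of the remaining traces whenever events sit on the frame grid, and
   order-sensitivity otherwise is confined to ±1-frame lag rounding.
   Sub-frame alignment is deliberately not attempted.
3. **Robust averaging.** Per-timepoint median and MAD scaled by 1.4826 (the
   asymptotic normal-consistency constant).
4. **Background and rescaling.** The post-event background is the mean of
   the median signal's local extrema inside a post-event window (extrema
   located as sign changes of an 11-point, order-2 Savitzky–Golay first
   derivative; order 3 would give identical coefficients). With no extrema
   the window mean is used. The profile is then mapped linearly so the
   background is 0 and the maximum 1, with the scaled MAD divided by the
   same factor (error propagation).

The onset of a normalized profile is defined operationally as the first
upward crossing of 10% of the peak (linearly interpolated); the Bzz1–Abp1
onset lag reported by the acceptance analysis is the difference of the two
channels' 10% crossings. With the preset kinetics its ground truth is
9.8–10 s.

Defaults: `max_lag = 20` frames; post-event window = the last third of the
trace (the presets leave ≥30 baseline frames there); `onset_fraction =
0.1`.

## Detection and tracking

Spot detection scans pixels above a cutoff brightest-first, keeps
neighbourhood maxima separated by at least `spot_radius`, and refines each
to the intensity-weighted centroid of its window (sub-pixel Gaussian
fitting is out of scope; weighted centroids localize the synthetic spots
to <0.1 px noise-free). The cutoff is the `intensity_percentile` quantile
of the frame's *background* distribution, estimated robustly as
`median + qnorm(p) · scaledMAD`: a plain sample quantile would ride up
with the number of bright patches in the frame and truncate dim assembly
phases, while the robust form stays at the stated noise percentile
regardless of patch density (default p = 0.9995, i.e. ~3.3σ). A
noise-free frame has MAD 0; there, anything above the flat background
(the frame minimum) is a candidate, which makes lifetime recovery on
noise-free renders exact.

Linking is greedy nearest-neighbour, closest pair first, with ties broken
towards the lowest patch id, links beyond `max_displacement` forbidden,
and gaps up to `max_gap` frames bridged. Greedy linking is not in general
the minimum-total-cost assignment; the two coincide when inter-patch
spacing exceeds per-frame motion, which is the regime of these movies, and
the test suite verifies the agreement against an exhaustive oracle on ≤4
patch scenes in that regime. Every detection ends up in exactly one
trajectory.

Lifetime is `(last − first + 1) · frame_interval`. Because events are open
intervals at their boundaries, an event of lifetime $L$ with a non-integer
onset occupies exactly $L/\Delta t$ frames, so noise-free recovery is
exact; under default noise the ~3.3σ cutoff truncates roughly
$0.03 A (a+d)$ seconds of dim tails, well under one frame for the preset
SNRs.

Average trajectories align each track on a fiducial — the disappearance
frame (default for movement profiles) or the intensity peak — and take
per-timepoint medians and scaled MADs of displacement and peak-normalized
intensity. Displacement is measured from each track's own position at the
fiducial so the profile is 0 at the alignment origin.

## Peak-intensity scaling

The epifluorescence pipeline smooths each trajectory's intensity series
with a 1-1-1 running mean (edges: mean of the two available samples),
estimates the dataset background as the median of per-trajectory minima,
subtracts it, and takes each trajectory's smoothed maximum as its peak.
Negative corrected peaks are kept, not clamped, so bias checks stay
honest. Note the smoothed maximum equals the true amplitude only when at
least three samples sit at the plateau; for the presets' 2 s plateaus at
1 s sampling the peak is shaved by up to ~2%, a bias shared by all strains
and absorbed by the scaling step.

A "dataset" is interpreted as one experiment (imaging session) containing
all strains — the only reading under which the brightest strain's
cross-experiment mean can be 0.99 rather than exactly 1.0. Within each
experiment all strain means are divided by the experiment's highest strain
mean; across experiments the per-strain mean of scaled means and the
average of scaled SDs are reported (the SD is the average within-experiment
SD, not the SD of experiment means). Image preprocessing for this path —
rolling-ball background subtraction and simple-ratio bleach correction —
is provided as grayscale opening with a ball-cap element (lateral radius
in pixels, height decoupled at 5% of the dynamic range so the ball rolls
under diffraction-limited spots) and per-frame mean ratioing.

## Classification and scission

Patches are classified per trajectory against a disk-shaped cell: outside
the cell → unassigned; median distance to the boundary beyond the membrane
band (default 0.3 µm — the band width is not published) → cytoplasmic;
otherwise persistent-PM if the lifetime reaches `persistence_fraction`
(default 0.9) of the movie, transient-PM if it spans at least `min_frames`
(default 3), else discarded as noise. Summaries report, per class, the
fraction of cells showing ≥1 patch of that class (classes co-occur, so
fractions may sum above 1) and mean patches per cell.

Scission is detected as the earliest frame where the centroid displacement
rate exceeds a threshold (default 0.05 µm/s; the preset jump gives
0.1 µm/s against Rayleigh step noise of ~0.014 µm/s) *and* the smoothed
intensity has fallen below `intensity_drop_fraction` (default 0.9) of its
peak, refined below the frame interval by interpolating the intensity-drop
crossing. Because patches appear asynchronously, absolute scission times
mix the onset distribution into any cross-strain comparison; the
comparison used in the acceptance analysis therefore references each
patch's scission to its own assembly onset, estimated by extrapolating the
line through the 25% and 75% rise crossings back to baseline
(`trajectory_onset()`) — unbiased for linear assembly regardless of the
assembly rate, so strains with different kinetics remain comparable.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the estimators assume:
two-channel events with a reference-channel lag, piecewise-linear pulses
with per-event amplitude and onset variability, Gaussian camera noise,
exponential photobleaching, diffuse background, membrane-band versus
interior positions, persistent/transient lifetimes, and an inward jump at
scission. It does not attempt evanescent-field optics, realistic cell
shapes, Poisson shot noise, focus drift, or the detection ambiguities of
crowded real movies; passing recovery tests here demonstrates correctness
of the estimators under the stated model, not performance on arbitrary
microscope data. Manual patch selection in the original workflow is
replaced by generator ground truth or the tracking module; this is a
substitution, not a claim of equivalence.

## Problem sizes and numerical choices

The validation suite runs the analyses at the published design points
chosen as: 3 simulated experiments × 5 Bzz1 presets × 200 trajectories for
peak scaling; 100 rendered events per strain for lifetime recovery; 68
two-channel pairs for the onset lag; 100 trajectories per Rvs167 preset
for scission timing; 300 cells for class fractions. Degenerate inputs fail
loudly: traces shorter than 3 samples, non-positive integrals, constant
signals in cross-correlation, zero-length kymograph lines, event windows
that overflow the movie, missing timing metadata on TIFF import. Image
round-trips store 16-bit samples with an affine scale in a JSON sidecar
(exact to 1/65535 of the dynamic range). Equidistant linking candidates
and cross-correlation ties resolve deterministically (lowest id; smallest
|lag|).
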