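Package: patchdyn
Title: Quantification of Endocytic Patch Dynamics in Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of clathrin-mediated endocytic
    patch dynamics in budding yeast time-lapse fluorescence microscopy.
    Provides a ground-truth synthetic movie and trace generator (two-channel
    patch events with configurable kinetics, photobleaching, camera noise and
    centroid motion), particle detection and greedy nearest-neighbour
    tracking, TIRF trace analysis (Simpson-integral normalization,
    cross-correlation alignment, median and consistency-scaled MAD profiles,
    Savitzky-Golay-derivative background estimation, 0-1 rescaling with
    error propagation), epifluorescence peak-intensity scaling (rolling-ball
    background, simple-ratio bleach correction, running-mean smoothing,
    median-of-minima background, per-dataset scaling), and classification of
    patches into persistent, transient and cytoplasmic classes with
    scission-event detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
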