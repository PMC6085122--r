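Package: cyclesizer
Title: Cell-Cycle Phase Segmentation and Size-Homeostasis Analysis from
    Histone-Reporter Traces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell-cycle progression and cell-size control in
    budding yeast from single-cell histone-reporter fluorescence time series.
    Provides a synthetic-lineage generator with known ground truth (phase
    durations, per-phase size-compensation strength, division asymmetry,
    first-order fluorophore maturation), anaphase-drop detection and
    piecewise-linear (plateau-ramp-plateau) segmentation of each cycle into
    G1/S/G2M/anaphase with explicit quality control, per-cycle variable
    extraction, Pearson correlograms and robust size-compensation slopes
    (Sizer -1 / Adder 0 / Timer +1 calibration), coefficient-of-variation and
    Fano-factor noise profiles along the cycle, and a noisy linear-map model
    of daughter birth size with analytic Fano prediction, intrinsic-noise
    fitting and convergence-rate analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
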