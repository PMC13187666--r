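Package: seedlingvc
Title: Seedling Hydraulic Vulnerability from Acoustic and Optical Drydown Data
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify drought-induced xylem embolism vulnerability of
    tree seedlings from bench-drydown experiments. Converts ultrasonic
    acoustic-emission (AE) event logs into per-minute activity series,
    Savitzky-Golay smooths them and extracts the water potential at peak
    acoustic activity (Psi_AEmax). Detects embolism events in optical
    vulnerability (OV) time-lapse image stacks by successive-frame
    differencing, accumulates embolized pixel area and fits Weibull
    vulnerability curves with Psi12/50/88 thresholds and bootstrap or profile
    confidence intervals. Includes piecewise-linear water-potential timelines
    from pressure-chamber readings, conduit anatomy metrics (hydraulic
    diameter, wall reinforcement), a statistics layer (ANOVA/Tukey letters,
    CI comparison, Pearson correlations), a command-line interface, and a
    fully synthetic drydown simulator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    truncnorm,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
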