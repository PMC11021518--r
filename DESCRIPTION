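Package: pulsevar
Title: Single-Cell Pulse-Labelling Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification and statistical analysis of cell-to-cell
    variability in single-cell protein synthesis rates measured by pulses of
    clickable methionine analogues (HPG, AHA) in fission yeast. Provides a
    calibrated stochastic generator of synthetic single-cell pulse-labelling
    datasets (stationary log-rate process with stretched-exponential
    autocorrelation, cell growth, measurement noise, background staining),
    mask-based image quantification, background correction and length
    normalisation, robust variability statistics (quartile coefficient of
    dispersion, coefficient of variation, per-length-bin profiles), dual-pulse
    decorrelation analysis with ranked-group regression-to-the-mean
    trajectories, and a replicate-thresholded variability screen across
    strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
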