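Package: trackmsd
Title: Mean Squared Displacement Analysis of Cell Migration Trajectories
Version: 0.1.0
Authors@R:
    person("trackmsd", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of 2-D cell migration tracks from
    time-lapse microscopy. Reads ImageJ Manual-Tracking-style track tables,
    computes per-cell motility metrics (speed, net displacement, path
    length, straightness), time-averaged and ensemble mean squared
    displacement (MSD) curves, and estimates the anomalous-diffusion
    exponent alpha by log-log regression with confidence intervals,
    classifying motility regimes (sub-diffusive, Brownian, super-diffusive,
    ballistic). Includes a seed-reproducible simulator of motion models
    (Brownian, ballistic, persistent random walk, fractional Brownian
    motion, circular, back-and-forth, mixtures), a targeted
    differential-expression overlap filter for migration gene panels, and a
    config-driven end-to-end pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
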