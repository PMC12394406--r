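Package: thermocycle
Title: Temperature Scaling of the Early Embryonic Cell Cycle Oscillator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how temperature shapes the early embryonic
    cell cycle. Implements the four temperature-scaling laws commonly fitted
    to biological rates and durations (Arrhenius, double-exponential,
    quadratic-exponential and power-law-exponential), with Q10 conversions,
    median-binned least-squares fitting and bootstrap confidence intervals
    for apparent activation energies. Simulates two-ODE (Cdk1/cyclin B
    relaxation oscillator) and five-ODE (mass-action Cdk1/Greatwall/PP2A/APC)
    cell-cycle models whose kinetic parameters scale with temperature,
    detects oscillation periods, phase durations, arrest states, nullclines
    and viable temperature ranges, and infers per-rate activation energies
    from phase-duration data by sequential Monte Carlo approximate Bayesian
    computation. Includes analysis of Cdk1-FRET-style droplet time series
    (cycle annotation, interphase slopes, averaged waveforms, biochemical
    assay rates) and synthetic-data generators emulating embryo,
    extract-droplet and biochemical-assay measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
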