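Package: amperodyn
Title: Physicochemical Modeling and Inversion of Amperometric Exocytosis Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parsimonious physicochemical models of vesicular exocytotic release
    monitored by single-cell amperometry. Provides forward simulation of current
    spikes from fusion-pore radius trajectories (Faraday-law flux under the
    quasi-steady-state intravesicular diffusion regime), analytic inversion of
    measured spikes into time-resolved release-rate and pore-radius trajectories,
    whole-sequence treatment of flickering (kiss-and-run) opening trains with a
    shared content ledger, semi-log exponential-tail classification, a
    two-compartment kinetic model of the biphasic intravesicular polyelectrolyte
    matrix with parameter fitting, a shrinking-pore consistency diagnostic,
    whole-trace baseline estimation and spike segmentation, a ground-truth
    synthetic data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
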