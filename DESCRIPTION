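Package: per2as
Title: Sense-Antisense Transcriptional Interference Model of the Per2
    Circadian Oscillator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic delay-differential-equation model of the mutual
    repression between the core clock gene Per2 and its antisense transcript
    Per2AS, implemented as head-on RNA polymerase collision (transcriptional
    interference). Provides the explicit RNAP on/off five-variable system and
    its quasi-steady-state three-variable reduction, a delay solver with the
    standard zero-history simulation protocol, oscillation metrics (period,
    amplitude, temporal average, phase relations, rhythmicity classification),
    scenario runners for promoter-mutant, knock-down and overexpression
    perturbations and for parameter sweeps and phase diagrams, and a seeded
    synthetic-rhythm generator for validating the metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
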