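Package: agestagelt
Title: Age-Stage Two-Sex Life Tables with Bootstrap Inference for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs age-stage two-sex life tables from individual-level
    daily life-history records of insect cohorts and estimates population
    parameters (net reproductive rate, intrinsic rate of increase, finite
    rate of increase, mean generation time) by solving the discrete
    Euler-Lotka equation. Standard errors and paired treatment comparisons
    use an individual-level bootstrap. Ships a calibrated synthetic cohort
    generator (wild-type and trehalose-transporter knockout presets for the
    diamondback moth), supercooling-point detection from 1 Hz cooling
    curves, trehalase-difference trehalose quantification, relative qPCR
    expression (Livak 2^-dCt and 2^-ddCt), thermal-survival summaries and
    Wilson proportion intervals, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
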