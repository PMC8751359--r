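Package: circlock
Title: Mechanistic Models of Circadian Clock Repression by Protein
    Sequestration and Phosphorylation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ordinary-differential-equation and stochastic models of the
    repression mechanisms that drive circadian oscillations: a reconstructed
    mass-action model of the cyanobacterial KaiABC post-translational
    oscillator, reduced KaiA-sequestration models with and without a
    transcription-translation feedback loop, the Kim-Forger activator
    titration model, and a repressor "phospholock" model of the eukaryotic
    clock with optional activator phosphorylation.  Includes stiff-capable
    ODE integration, exact stochastic simulation (Gillespie), two
    oscillation detectors (spectral and event-location), seeded Monte-Carlo
    parameter samplers, and the analyses built on them: oscillation-region
    scans over binding affinity and phosphorylation strength, stoichiometric
    balance conditions, repression-function sensitivity curves, and
    steady-state stoichiometric-ratio distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
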