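Package: preactive
Title: Kinetic Detection of Pre-Active Intermediate States in Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for detecting pre-active
    (intermediate, closed-channel) conformations of pentameric ligand-gated
    ion channels from ensemble kinetics.  Provides a pH-dependent four-state
    gating scheme simulator with fluorescence-quenching, voltage-clamp current
    and liposome thallium-flux observables; multi-exponential decomposition of
    stopped-flow fluorescence traces with dead-time phase accounting;
    log-binned clustering of fitted time constants into kinetic phases;
    stretched-exponential analysis of liposome flux assays; Hill dose-response
    fitting and pH50 comparison across readouts; and structural distance checks
    (C-beta distances, minimal fluorophore-quencher distances, Kabsch
    superposition) that anchor fluorescence sensors to structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    MASS,
    Matrix,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
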