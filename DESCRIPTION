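Package: jakstatswitch
Title: Bistable JAK/STAT Signaling and Border-Cell Fate Determination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modeling toolkit for the bistable cross-repression
    switch between Apontic (APT) and Slow Border Cells (SLBO) downstream of
    JAK/STAT signaling, which decides whether a Drosophila egg-chamber
    follicle cell becomes a motile border cell or remains stationary.
    Implements the full 15-variable ordinary differential equation model of
    the pathway, its staged quasi-steady-state reduction to a minimal
    three-variable model in STAT, APT and SLBO, stiff time integration and
    fate classification, steady-state finding with stability analysis,
    pseudo-arclength continuation in the Unpaired (UPD) ligand level with
    fold (limit-point) detection, per-parameter bistable-range scanning,
    basin-of-attraction grid classification with separatrix surface
    fitting, and scripted in-silico experiments (miRNA-induced delay of
    STAT activation, STAT knockdown, APT initial-condition sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
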