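Package: enfea
Title: Ensemble End-Point and Alchemical Binding Free Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Analysis of ensemble-based binding free energy calculations for
    congeneric ligand series: MMPBSA-style end-point estimation from replica
    ensembles (the 1traj protocol and its receptor-adaptation variant
    1traj-ar), ensemble thermodynamic integration over lambda windows with
    bootstrap uncertainties, perturbation-network cycle-closure and offset
    diagnostics, and affinity-ranking evaluation against pIC50 data. Includes
    synthetic-data generators with planted ground truth, among them an
    analytically solvable harmonic alchemical model, so the whole pipeline is
    testable without molecular dynamics trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
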