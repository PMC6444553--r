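Package: dualfep
Title: Dual-Topology Free Energy Perturbation Workflow Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dual-topology alchemical specifications for ligand pairs,
    prepares spherical-boundary simulation systems, generates lambda-window
    molecular dynamics input decks in the Q text dialect, and analyzes
    per-window energy samples into relative free energies via Zwanzig
    exponential averaging, overlap sampling, and the Bennett acceptance
    ratio, with replicate statistics, Born charging corrections,
    thermodynamic-cycle combination, and benchmark reporting (MAE, Pearson
    R-squared with Fisher-z confidence intervals, ordinary least squares).
    Includes a synthetic-data module (Gaussian work distributions and a
    one-dimensional harmonic-oscillator pair with analytic free energies)
    so the full pipeline can be validated without a molecular dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
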