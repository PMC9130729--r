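Package: nscdyn
Title: Stochastic Population Dynamics of Neural Stem Cells in the Zebrafish Pallium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-driven stochastic simulation of a labeled neural-stem-cell
    (NSC) cohort in the adult zebrafish pallium: a six-reaction network over a
    reservoir pool, an operative pool and post-mitotic neurons, with
    equilibrium analysis, learning-modulated rates during training windows, a
    maturation death checkpoint with activity-dependent rescue, per-lineage
    division counting, a deterministic mean-field oracle, a named scenario
    battery, and a synthetic per-fish cell-count generator for model-to-data
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
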