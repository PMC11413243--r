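Package: qhtscreen
Title: Quantitative High-Throughput Drug Screen Analysis for Cell Viability Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative high-throughput drug screens
    read out as per-well cell counts on 384-well microplates. Implements loess
    correction of within-plate spatial (edge) effects with exclusion of highly
    toxic wells, per-plate normalisation to the DMSO vehicle-control median,
    viability binning, per-cell-line robust Z-scoring, tiered selection of
    cancer-specific cytotoxic hits against a normal-cell counter-screen,
    secondary-validation assessment, and assay quality control (Z-prime
    factor, percent coefficient of variation). Includes a synthetic-screen
    generator with known ground truth (Hill-curve compound effects, spatial
    and batch artefacts, overdispersed counting noise) so every stage is
    testable without access to raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
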