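Package: luces
Title: Land-Use and Climate Scenario Simulation of Ecosystem Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled scenario pipeline for plateau urban agglomerations:
    multi-objective linear programming of 2030 land-use demand (ecological
    protection vs economic development vs Markov natural-increase
    projection), patch-generating cellular-automata spatial allocation
    driven by random-forest land-expansion suitability, four
    ecosystem-service models (water yield, carbon stock, habitat quality,
    RUSLE soil retention), and spatial trade-off/synergy analysis via
    Spearman rank correlation and geographically weighted regression.
    Includes a seeded synthetic-landscape generator (spectral-noise
    terrain, elevation-dependent climate, paired land-use maps with a
    known transition process) so the whole pipeline is testable without
    external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    ranger,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
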