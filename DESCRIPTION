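Package: chemoatlas
Title: Multi-Cohort Chemokine Expression Profiling Across the Colitis-to-Colon-Cancer Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vote-counting meta-analysis of chemokine family expression across
    independent transcriptomic cohorts spanning five harmonized disease stages
    (healthy control, inflammatory bowel disease, adenoma, primary carcinoma,
    metastasis). Ingests series-matrix style expression data, collapses probes
    to genes, runs per-dataset equal-variance t-tests with Benjamini-Hochberg
    correction, aggregates significance calls into a ratio-of-significant-
    difference score matrix, classifies genes into four expression-pattern
    groups by fold-change quadrants, clusters score profiles, and correlates
    mouse colitis and colon-cancer model fold changes against human cohorts.
    Includes a synthetic multi-cohort generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
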