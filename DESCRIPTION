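Package: qams
Title: Single-Marker Quantitation of Sichuan Pepper Alkylamides by HPLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Quantitative Analysis of Multi-components by a Single
    Marker (QAMS) applied to HPLC determination of the hydroxy-sanshool
    alkylamides of Sichuan pepper, with Nonivamide as a surrogate reference
    standard. Provides seeded simulation of annotated chromatograms and peak
    tables, baseline estimation, peak detection and integration, linear
    calibration with LOD/LOQ, relative correction factor (RCF) estimation and
    durability assessment over instrument-condition grids, relative retention
    time (RRT) peak assignment, external-standard and single-marker
    quantitation, and method-equivalence testing via standardized mean
    differences (SMD).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
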