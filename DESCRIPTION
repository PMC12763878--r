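Package: ltfassay
Title: Ex Vivo Live Tumor Fragment Immunotherapy Response Analysis
Version: 0.1.0
Authors@R: person("Platform", "Analytics", email = "dev@example.org", role = c("aut", "cre"))
Description: Computational pipeline for an ex vivo live-tumor-fragment (LTF)
    immunotherapy response platform. Provides in silico tissue fragmentation
    and random pooling to quantify sampling heterogeneity of clustered immune
    cell distributions; multiplex cytokine quantitation preprocessing with
    LLOQ/ULOQ censoring rules and panel QC metrics; a cross-well response
    statistic based on MAD-trimmed modified Z-scores with Ward clustering and
    biomarker enrichment; a sequential-treatment slope fold-change statistic
    with three-band classification for core needle biopsies; and a
    synthetic-data generator with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
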