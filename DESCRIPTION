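Package: speceffect
Title: Spectrum-Effect Relationship Screening for Herbal Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spectrum-effect relationship analysis of herbal
    extracts: alignment of chromatographic fingerprint peak tables into a
    normalized characteristic-peak matrix, reduction of raw bioassay data
    to activity endpoints (enzyme inhibition rates, four-parameter logistic
    IC50, broth-microdilution MIC, inhibition-zone summaries), gray
    relational analysis (Deng's relational degree) and NIPALS partial least
    squares regression with VIP and leave-one-out Q2, a consensus rule that
    nominates putative active peaks, and offline network-pharmacology
    statistics (target-set intersection, degree ranking, hypergeometric
    enrichment, component-target-pathway-disease network assembly).
    Includes synthetic-data generators that emulate the full study design
    for validation and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
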