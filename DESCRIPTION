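Package: oncorewire
Title: Link-Weight Rewiring of Signaling Networks Across Disease States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying the reorganization of a typed
    signaling network across biological states (normal, adenoma, carcinoma)
    driven solely by changes in gene expression. Per-state link weights are
    built from median expression abundances, weighted network diameters are
    computed under three directivity conventions, extensively overlapping
    modules are detected with an influence-function community landscape, and
    pathway-level statistics (medians, paired Wilcoxon signed-rank tests,
    weighted degrees, extreme-link counts) are derived per gene set. A
    synthetic-data generator produces typed networks and three-state
    expression matrices with planted effects for recovery testing, and a
    noise-robustness driver re-runs the analysis under multiplicative
    abundance perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
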