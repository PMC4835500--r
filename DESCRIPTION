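Package: zanthotools
Title: Chemistry, ITS2 Barcoding and Habitat Suitability of Szechuan Pepper Cultivars
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reproducible four-stage analysis for Zanthoxylum (Szechuan
    pepper) cultivar characterisation: pericarp chemistry (volatile-oil and
    non-volatile ether-extract contents, one-way ANOVA, principal component
    analysis), ITS2 DNA-barcode analysis (Kimura 2-parameter distances with
    pairwise deletion, barcoding-gap and diagnostic-site analysis,
    neighbor-joining trees with bootstrap support), chemo-ecological
    correlation via NIPALS partial least squares regression with
    variable-importance-in-projection scores, and fuzzy
    ecological-envelope habitat-suitability mapping on gridded
    environmental layers. Includes deterministic synthetic-data generators
    so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
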