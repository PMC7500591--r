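Package: phyllodiff
Title: Differential Functional-Annotation Analysis for Phyllosphere
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing functional gene-family annotation
    profiles of leaf-surface (phyllosphere) metagenomes between
    treatment groups at small replicate numbers. Implements
    contaminant filtering against mock and soil control samples, TMM
    and median-of-ratios normalization, a two-stage differential test
    (elastic-net feature screening followed by per-annotation negative
    binomial fits with moderated dispersion), simulation-based false
    discovery rate calibration of the significance threshold,
    cross-site comparison of significant Gene Ontology term sets, and
    treatment-effect estimation for plant traits. A synthetic-data
    module generates zero-inflated overdispersed count tables with
    known ground truth so that every stage is testable without
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
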