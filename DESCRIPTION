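Package: wmniche
Title: White-Matter Niche Transcriptomic Signatures and Quantification for
    Glioma Invasion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how glioblastoma cells respond to
    the white-matter microenvironment. Derives cell-type gene signatures from
    reference expression atlases (coefficient-of-variation gene selection and
    K-means clustering with a discrimination-margin rule), performs
    region-specific negative-binomial differential expression with
    median-of-ratios normalisation, clusters regulated genes and scores
    cluster-by-signature overlaps with one-sided Fisher exact tests under
    Benjamini-Hochberg or Bonferroni correction. Also implements the
    morphometric and image-derived quantifications used in such studies:
    Feret diameters and myelin g-ratios, decompaction and degeneration
    calls, nuclear-intensity tiering, axon-contact and myelin-disruption
    rules, invasion and migration-track metrics, plus seeded synthetic-data
    generators with known ground truth for every stage.
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
    grDevices,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
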