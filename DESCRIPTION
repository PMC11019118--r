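Package: chronoscreen
Title: Circadian Rhythm Screening, OPLS Time-of-Day Modeling, and Fly
    Sleep Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for age-related changes in circadian metabolite
    cycling and sleep in Drosophila. Screens omics time courses for 24-hour
    rhythms with a Jonckheere-Terpstra-Kendall (JTK) statistic and exact
    permutation null, applies Benjamini-Hochberg false-discovery control, and
    summarises overlap between age groups. Fits orthogonal projections to
    latent structures (OPLS) regressions of the scaled metabolome on
    collection time with 7-fold cross-validation and CV-ANOVA model
    significance. Ingests Trikinetics DAM2 activity-monitor files, filters
    count artifacts, scores sleep by the 5-minute inactivity definition,
    computes FFT rhythm power, and runs the two-control statistical harness.
    Quantifies ratiometric CaLexA calcium and mito-roGFP redox imaging.
    Includes seeded synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    tiff,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
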