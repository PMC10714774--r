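Package: oralhsct
Title: Longitudinal Multi-Site Oral Microbiota Dynamics and Outcomes in
    Allogeneic HSCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal oral-microbiota profiling of
    allogeneic hematopoietic stem-cell transplant (allo-HSCT) recipients
    sampled at three oral sites (gingival crevicular fluid, oral mucosa,
    supragingival biofilm) across five clinical timepoints. Provides ranked
    subsampling (SRS) depth normalization, Gini-Simpson diversity with
    per-patient resistance/resilience/stability indices, a weighted UniFrac
    kernel with PCoA ordination, PERMANOVA and distance-to-centroid
    dispersion statistics, bloom (dominance) detection, antibiotic-exposure
    metrics (length and days of therapy), recovery-to-baseline
    classification, and Cox / Fine-Gray competing-risks association of
    recovery with clinical outcomes. A seeded synthetic-cohort generator
    reproduces the statistical structure the analysis assumes (diversity
    nadir and maximal inter-patient dispersion at engraftment, injected
    blooms, antibiotic timelines, recovery-linked survival), so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cmprsk,
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
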