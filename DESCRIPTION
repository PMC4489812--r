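Package: probionir
Title: Aquaphotomics Screening of Probiotic Lactobacilli from NIR Growth Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotyping Lactobacillus strains from time-resolved
    near-infrared (NIR) growth-monitoring spectra of their cultures. Implements
    the full chemometric chain used in aquaphotomics screening of probiotic
    strength: Savitzky-Golay smoothing, multiplicative scatter correction and
    Pareto scaling as a leakage-safe fit/apply pair; principal component
    analysis, NIPALS partial least squares regression and orthogonal projection
    to latent structures discriminant analysis (OPLS-DA) built from their
    algorithms; moving-window PCA over cultivation time with a group-separation
    ratio to pick the optimal analysis window; one-strain-out cross-validation
    and independent hold-out validation; aquagram water-spectral fingerprints at
    the water matrix coordinates; and a reference-PCA probioticity score from
    growth, bile-tolerance and acid-stress phenotypes. A synthetic spectra
    generator emulates instrument-shaped growth experiments with planted group
    structure for end-to-end testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
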