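Package: vigorspec
Title: Seed-Vigor Discrimination from Laser-Induced Breakdown Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and chemometric analysis of laser-induced breakdown
    spectroscopy (LIBS) data for discriminating high- and low-vigor forage
    seed lots. Provides a synthetic emission-spectrum generator with
    vigor-linked Mg/Ca/K line effects, desirability-based optimization of
    acquisition conditions over a two-level three-factor design with center
    point (signal-to-background ratio, individual and overall desirability),
    standard normal variate preprocessing, spectral angle mapper outlier
    rejection, and a PCA plus leave-one-out cross-validated classification
    workflow (KNN, LDA, QDA, SVM) with grid-search heat maps and external
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
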