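Package: adadetect
Title: Certified Shortcut Detectives for Acquisition-Dependent Attributes in Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects intrinsic, acquisition-dependent shortcuts (global image
    contrast and sharpness) in binary-labeled medical image datasets.
    Constructs shortcut-detective training sets from a pool of finding-free
    images by perturbing one randomly assigned class, trains small
    convolutional ensemble classifiers, certifies them with a two-exam
    protocol (chance-level AUC on a shortcut-free cohort, near-perfect AUC
    when the known perturbation is injected into either class), and deploys
    certified detectives to audit curated datasets via AUC with stratified
    bootstrap confidence intervals. Ships a chest-radiograph phantom
    generator so the whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    digest,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
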