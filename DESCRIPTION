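Package: cogstruct
Title: Latent Structure of Cognition from Behavior and Task Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bottom-up latent-structure analysis of cognitive task batteries:
    maximum-likelihood exploratory factor analysis with geomin (oblique)
    rotation and a full structural-equation fit-statistic suite (chi-square,
    CFI, TLI, RMSEA, SRMR, Heywood diagnostics); masked spatial correlations
    between task activation z-maps with positive-activation intersection
    masks and domain conjunction masks; and brain-behavior coupling between
    domain-mask beta estimates and composite task performance. Includes a
    synthetic-data generator that plants a known oblique factor structure in
    behavioral scores and a known network structure in task maps, so the
    whole pipeline is testable end to end against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
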