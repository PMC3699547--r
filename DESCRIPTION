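Package: idaconn
Title: Intrinsic Discriminant Analysis of Resting-State Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass discriminative analysis of whole-brain resting-state
    functional connectivity. Builds Pearson-correlation edge features over a
    116-region parcellation, reduces dimensionality with intrinsic discriminant
    analysis (a perturbed generalized eigenproblem over class-common and
    individual scatter), classifies subjects with one-against-rest linear
    support vector machines under leave-one-out cross-validation, and maps
    classifier weights back to edge space to rank discriminative connections
    and build convergent/divergent connection sets. Includes a synthetic
    multi-group BOLD time-series generator with controlled covariance
    perturbations so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
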