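Package: ctrecon
Title: Iterative Filtered Back Projection for Low-Dose CT Simulation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a first-order iterative approximation to the
    generalized (Moore-Penrose) inverse of a parallel-beam CT projection
    operator, accelerated by substituting filtered back projection (FBP) into
    the update. Includes seeded 2-D phantom generators, an exact Siddon-style
    forward projector with its adjoint and an explicit sparse system matrix,
    windowed-ramp FBP, the image-domain iterative-FBP reconstruction loop,
    a Poisson low-dose acquisition simulator, image-quality metrics (MSE,
    ROI noise, SNR, contrast), and worked-example two-group outcome
    statistics from a printed contingency table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
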