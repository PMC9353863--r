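Package: clawmech
Title: Structure-Function Analysis of Insect Claws from SEM Images and
    Nanoindentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the attachment apparatus of climbing
    insects such as bamboo weevils. Implements non-local means (NLM)
    denoising of scanning electron micrographs with an improved
    cosine-windowed patch weight, multiscale B-spline wavelet
    modulus-maxima edge detection alongside five classical operators,
    least-squares fitting of claw boundary curves (second-order Fourier,
    Gaussian and polynomial families) with analytic curvature profiling,
    rigid-body models of claw-tip adhesion on particulate surfaces
    (self-locking condition, pressure-angle geometry and two-contact
    force distribution), and Oliver-Pharr analysis of nanoindentation
    load-displacement records. A synthetic-data module generates claw
    phantom images, boundary point sets and indentation curves with
    known ground truth so the whole pipeline is testable without
    microscope access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
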