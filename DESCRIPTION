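Package: ellipore
Title: Ellipsoidal Probe Profiling of Ion-Channel Pores and Conductance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Probe-based annotation of ion-channel and nanopore permeation
    pathways. A spherical probe is maximised slice by slice along the channel
    axis (HOLE-style simulated annealing), then each sphere is inflated into a
    maximal in-plane ellipse by staged derivative-free optimisation, capturing
    pore asymmetry with two radii per slice. The two-radius profile feeds a
    physical conductance heuristic: a stacked-cylinder Ohmic resistance model
    with either bulk electrolyte conductivity (Nernst-Einstein form) or a
    radius-dependent double-sigmoid conductivity model whose parameters are
    fitted to training conductances. Includes generators for armchair carbon
    nanotubes with controlled, area-preserving ellipticity and bead-wall test
    pores with analytic ground truth, so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
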