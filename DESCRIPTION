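Package: stemdish
Title: Stochastic Lattice Model of Stem-Cell Decision-Making and Tissue
    Pattern Maintenance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a hypothetical adult tissue as a two-dimensional dish
    of stem (S), progenitor (P) and two terminally differentiated cell types
    (A, B) whose fates are decided by intracellular multistable regulatory
    switches and biased by diffusing intercellular signals.  Provides an
    exact Gillespie (SSA) engine over the 24 reaction channels of the model
    (determinant synthesis and degradation with Hill kinetics, division with
    binomial partitioning of fate determinants, stochastic S/P
    interconversion, cell movement, signal production, decay and lattice
    diffusion), deterministic analysis of the bistable and tristable
    switches (fixed points, attractor basins, fate classification), the
    deterministic mean-field population model with closed-form steady state
    and Jacobian stability criteria, a template/penalty sliding-filter score
    of spatial pattern similarity, and experiment recipes for dish-geometry
    sweeps and injury-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
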