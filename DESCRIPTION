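Package: growpath
Title: Growing-Path Construction and Optimization of Minimum Free Energy Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and optimizes transition paths on multidimensional
    free energy surfaces in collective-variable space. A path is grown
    snapshot by snapshot from the reactant toward the product under a blend
    of the free energy gradient and the pull toward the product, then
    refined by perpendicular-gradient string optimizers (fixed-step and
    variable-step steepest descent, limited-memory quasi-Newton with step
    control and angle-based smoothing), with arc-length reparametrization
    and a root-mean-square perpendicular-gradient convergence metric. Free
    energy gradients come from analytic test surfaces, gridded surfaces
    read from delimited text, or a toy constrained-dynamics engine that
    estimates the thermodynamic mean force as the ensemble average of SHAKE
    Lagrange multipliers, with the metric-determinant correction term.
    Free energy profiles along a path are recovered by thermodynamic
    integration of the tangential mean force.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
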