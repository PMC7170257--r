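Package: tumorfb
Title: Free-Boundary PDE Simulation of Melanoma Under Anti-PD-1 and
    Anti-TNF-alpha Combination Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Radially symmetric free-boundary reaction-diffusion model of a
    melanoma tumor interacting with dendritic cells and cytotoxic T cells
    under immune-checkpoint (PD-1/PD-L1, TIM-3/Gal-9) inhibition, treated
    with anti-PD-1 and anti-TNF-alpha antibodies.  Provides the model
    constants with their derivation rules (half-saturation closures,
    cube-root molecular-weight diffusion scaling, half-life conversion), a
    moving-mesh explicit-Euler solver on a nonuniform radial grid with a
    free boundary advected by the cell velocity, pulse-decay dosing
    schedules (mouse day lists and 3-week human cycles S1/S2/S3), tumor
    volume reduction rate (TVRR) efficacy maps over dose grids, and Latin
    hypercube / partial rank correlation (PRCC) global sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
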