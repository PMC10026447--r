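Package: endfeet
Title: Geometry and Permeability of the Astrocyte Endfoot Sheath on Brain Microvessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative stochastic-geometry model of the astrocyte endfoot
    sheath that tiles the outer surface of cortical microvessels. Endfoot
    patterns are simulated as periodic Voronoi tessellations of hard-core
    point processes on the unrolled (cylindrical) vessel surface, yielding
    inter-endfoot gap area fractions, cross-sectional gap counts and
    per-cell area distributions. From the gap geometry the package derives
    membrane transport coefficients (filtration coefficient Lp via a
    parallel-plate channel model, diffusion membrane coefficient CM with
    Renkin hindrance) and corrects the projection bias inherent to
    two-dimensional endfoot-area measurements. A synthetic cortical
    microvascular network generator, a Poiseuille pressure solver with
    in-vivo apparent blood viscosity, pressure-based arterial/venous
    classification and depth-layer aggregation map the coefficients onto
    vessel networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deldir,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
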