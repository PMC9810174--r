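Package: aggresim
Title: Individual-Based Simulation of Microbial Aggregate Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Individual-based model of the maturation of microbial aggregates
    (granules, flocs, biofilm colonies) in two dimensions. Soluble substrates
    diffuse through the aggregate and a surrounding boundary layer and are
    consumed or produced by discrete Monod-kinetic cells; cells grow, divide,
    shove one another apart, become inactive under starvation, and can be
    detached beyond a maximum radius. Ships ecology presets for neutralism,
    competition, commensalism and mixed commensalism-plus-competition
    communities of three equal-fitness populations, a pseudo-steady-state
    reaction-diffusion solver, and analysis statistics: relative abundances,
    fitness medians, angular colony sections, the biological Thiele modulus,
    the eco-interaction modulus, and spatial stratification indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
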