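Package: pedbottleneck
Title: Velocity-Based Simulation of Pedestrian Bottleneck Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of pedestrian flow through bottlenecks using a
    collision-free speed model: hard-disc agents whose speed is a function of the
    spacing to the nearest agent in their headway, steered by a floor field obtained
    from the Eikonal equation with wall-avoidance slowness, with white noise on the
    desired direction. Includes corridor and hopper (45-degree funnel) geometries,
    scenario generation with randomised initial densities, and a measurement suite:
    Voronoi density time series and fields, Gaussian-kernel density maps, interaction
    angle distributions, waiting-time power-law exponents, and exit time-gap
    statistics. Command-line entry points allow running single simulations, parameter
    sweeps over corridor width and motivation, and trajectory-file analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
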