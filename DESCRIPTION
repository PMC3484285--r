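Package: flowgrid
Title: Optic-Flow Driven Self-Motion Estimation and Grid-Cell Firing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how optic flow alone can drive entorhinal grid-cell
    firing in a foraging rat. Provides a synthetic (and file-based) rat
    trajectory source with the standard three-rule cleaning of tracked
    positions, an analytic spherical-camera model of visual image motion over
    a circular ground platform, Gaussian flow-noise corruption, a template
    model that decodes linear and rotational self-motion from single flow
    fields by rotation-annihilating Gaussian-tuned matching, forward-Euler
    path integration with an optional periodic reset to ground truth, a
    velocity-controlled oscillatory-interference model of grid-cell spiking,
    and rate-map scoring (smoothed occupancy-normalised maps, spatial
    autocorrelograms, gridness scores, and k-means grid-spacing estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
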