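Package: canopymix
Title: Light Partitioning in Virtual Wheat-Pea Intercrop Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the sharing of diffuse light between wheat and pea in
    virtual intercrop canopies. Builds seeded parametric 3D mock-ups of six
    contrasting pea genotypes (leafy and semi-leafless) and of a wheat stand,
    assembles them into row-intercrop scenes, computes per-species interception
    of diffuse photosynthetically active radiation by first-hit ray casting over
    a discretized Uniform Overcast Sky, and compares the computed light shares
    with the turbid-medium (well-mixed canopy) prediction based on leaf area
    index and foliage inclination. Also provides Schnute growth-curve fitting of
    phytomer-appearance kinetics, with derivative-based maximum appearance
    rates, used to parameterize plant development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
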