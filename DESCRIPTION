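Package: restoscape
Title: Systems Framework for Evaluating Tree-Restoration Scenarios in
    Forest-Agricultural Landscapes
Version: 0.1.0
Authors@R:
    person("restoscape", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating riparian tree-restoration scenarios in
    mixed forest-agricultural landscapes along three socio-ecological
    pathways: microclimate regulation (canopy closure effects on ground
    temperature, fluorescence and crop yield), biodiversity (linear
    discriminant models of richness classes and threatened-species
    presence driven by landscape-configuration covariates), and
    human-wildlife conflict (crop-raiding risk surfaces), together with a
    composite household wellbeing index and ordinal models of perceptions
    of nature. Includes a seeded synthetic-landscape generator, a raster
    covariate engine (exact Euclidean distance transforms, circular focal
    statistics, percent-cover windows), a riparian-buffer scenario
    engine, from-scratch statistical cores (Wilks' Lambda, greedy forward
    discriminant selection, LDA, Moran's I, proportional-odds and
    random-intercept models) and baseline-versus-scenario change
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    splines
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
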