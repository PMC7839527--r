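Package: lianacomp
Title: Liana-Tree Competition: Demographic Simulation, Trait
    Meta-Analysis and Uncertainty Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale modelling chain for disentangling water versus
    light competition between lianas (woody vines) and tropical trees. The
    package couples a cohort/patch demographic vegetation simulator with a
    liana plant functional type (climbing height restriction, plant
    hydraulics, Beer-Lambert light competition, layered soil-water
    competition) to a Bayesian random-effects trait meta-analysis and a
    one-at-a-time sensitivity workflow with Hermite-spline response
    functions, elasticities, variance decomposition into water- versus
    light-related parameter classes, and Monte-Carlo ensembles. Synthetic
    generators emulate seasonally dry tropical forest inventories,
    meteorological forcing and trait datasets so the whole chain runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
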