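Package: soilrisk
Title: Spatially Misaligned Ecological Regression of Soil Trace Elements and
    Municipal Cancer Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for small-area ecological analysis linking point-sampled
    topsoil element concentrations (e.g. arsenic, chromium) to municipal
    mortality. Implements indirect standardisation of expected deaths,
    empirical variogram estimation and ordinary kriging of log concentrations
    onto municipal centroids (plug-in exposure, "approach A"), finite-element
    SPDE representation of Matern Gaussian fields on a triangulated mesh, and
    joint Bayesian estimation of the latent exposure field together with a
    Poisson Besag-York-Mollie disease model for spatially misaligned data
    ("approach B"). Includes quartile and trend exposure coding, confounder
    adjustment, a Bayesian difference of group means, a synthetic study
    universe generator with known ground truth, and a reproducible pipeline
    driver. All samplers are seed-deterministic block Metropolis-Hastings with
    sparse-matrix Gaussian-approximation proposals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
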