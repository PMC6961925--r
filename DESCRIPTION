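Package: elevrich
Title: Geometric-Constraints Null Models and Richness Statistics for
    Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing species richness along banded elevational
    gradients: weighted random-placement (geometric constraints) null models
    with range cohesion or scatter and hard or soft domain boundaries, exact
    placement enumeration and Monte-Carlo richness prediction, a
    range-contiguity (matrix-fill) standardized effect size test,
    deviance-ratio model comparison, sample-based incidence rarefaction,
    the Chao2 richness estimator, Moran's I with permutation inference,
    Poisson mixed-model fitting with AICc selection, a synthetic community
    and survey generator, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
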