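Package: percebe
Title: Larval Dispersal Kernels, Upwelling Indices and Catch-Rate Models
    for a Coastal Barnacle Fishery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Biophysical analysis of gooseneck barnacle (Pollicipes
    pollicipes) larval dispersal and fishery productivity on an
    upwelling-influenced coast.  Converts moored current-profiler (ADCP)
    velocity time series into stage-structured advective and stochastic
    dispersal length scales, builds two-dimensional Gaussian dispersal
    kernels with a sticky coastal boundary and derives recruitment
    metrics from them; computes the Bakun daily upwelling index from
    coastal wind records, its GAM seasonal cycle and the
    season-integrated upwelling index; and fits lagged upwelling/quota
    regression models of catch per unit effort with AIC-based model
    selection and variance partitioning.  A seeded synthetic-data module
    generates current, wind and catch datasets with known ground truth
    so that the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    mgcv,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
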