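Package: sdmplanr
Title: Presence-Background Niche Modelling and Systematic Conservation Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for species distribution modelling and
    systematic conservation planning on geographic raster grids. Fits
    presence-background maximum-entropy habitat models with linear,
    quadratic, product, hinge and threshold features and L1 regularization,
    tunes the regularization multiplier and feature combination over a grid
    with small-sample AICc, evaluates models with AUC, the true skill
    statistic, Cohen's kappa, percent contribution, permutation importance
    and jackknife gains, classifies suitability surfaces into habitat
    classes with spherical area accounting, computes range-change maps and
    centroid shifts, selects reserve networks by simulated annealing under
    a representation target with a boundary length modifier, and quantifies
    conservation gaps against protected-area polygons. A synthetic
    landscape generator supplies spatially autocorrelated predictors,
    a configurable unimodal niche, occurrence samples and protected-area
    polygons so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, geosphere
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
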