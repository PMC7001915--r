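Package: richworld
Title: Species Richness Modelling from Environmental Drivers with
    Interpretable Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for modelling gridded species
    richness from environmental drivers. Generates synthetic equal-area
    worlds with known driver-richness structure; screens point occurrence
    records by a resampled range-recovery statistic and rarefaction
    diagnostics; engineers model features from driver layers and monthly
    series, including Morlet-wavelet 6- and 12-month seasonal-intensity
    metrics; fits a small feed-forward neural network (rectifier units,
    dropout, momentum SGD) to ln(x+1)-transformed richness; and interrogates
    the fitted model with bootstrapped noise-perturbation variable
    importance, partial dependence, resampled loess ensembles, residual
    maps, zonal profiles and empirical semivariograms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
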