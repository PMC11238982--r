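Package: oceandiv
Title: Basin-Scale Biodiversity Analysis of Gridded Marine Occurrence Records
Version: 0.1.0
Authors@R: person("Analysis", "Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for basin-scale macroecological analysis of marine species
    occurrence records on a degree grid: record cleaning and taxonomic
    harmonization, presence-absence matrix construction, alpha/Shannon/beta
    diversity with Sorensen partitioning into turnover and nestedness,
    Getis-Ord G* hot-spot detection and Moran's I autocorrelation, sample-size
    based rarefaction and extrapolation with sampling-coverage diagnostics,
    environmental predictor construction with random-forest two-stage variable
    selection, generalized additive models with residual-autocovariate terms
    and BIC selection, and generalized dissimilarity modelling with monotone
    I-spline transforms and PCA/RGB composition mapping. Includes a synthetic
    occurrence-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
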