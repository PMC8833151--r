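Package: arbodiv
Title: Asymptotic Tree Species Richness Estimation from Gridded Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric and parametric estimation of regional and global
    species richness from mixed abundance/occurrence survey records pooled
    into ~1-degree grid-cell sampling units. Implements Good-Turing sample
    coverage, the bias-corrected Chao2 estimator with log-normal confidence
    intervals, a false-unique ("true singletons") adjustment of the unique
    count and the resulting adjusted Chao2, Fisher's log-series alpha with
    the classical richness equation and a Kolmogorov-Smirnov goodness-of-fit
    test, exact sample-based rarefaction with Chao2-anchored extrapolation,
    rarity indices, and richness partitioning into shared and endemic
    components over all subsets of regions. A synthetic multi-region world
    generator with log-series abundance structure, spatially clustered
    ranges, and an injectable misidentification process supports validation
    without access to restricted survey databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'logseries.R'
    'synthetic-world.R'
    'occurrence-grid.R'
    'estimators.R'
    'fisher.R'
    'accumulation.R'
    'rarity.R'
    'partition.R'
    'pipeline.R'
    'io.R'
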