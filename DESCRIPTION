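Package: fvtdry
Title: Function-Valued Trait Analysis of Soil Dry-Down Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of plant trait responses to a continuous soil-moisture
    gradient as function-valued traits. Provides per-trait reaction-norm model
    selection by bidirectional stepwise AIC over a full fixed-effects model
    with quadratic and natural-spline environmental terms and their
    genotype interactions; prediction of genotype trait means along a
    gravimetric soil-moisture grid; genetic correlations between traits as
    functions of soil moisture; a multivariate plasticity statistic (Euclidean
    distance between consecutive scaled multivariate phenotypes) with species
    contrasts and trait-space PCA; and G-matrix evolutionary-constraint
    statistics (number of effective dimensions, maximum evolvability, total
    genetic variance). A synthetic dry-down experiment generator with known
    genotype-specific reaction norms makes the whole pipeline testable
    without greenhouse data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
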