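Package: zoneclines
Title: Geographic Cline Analysis for Hybrid Zones
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing hybrid zones between two parental taxa from
    georeferenced individuals: construction of a one-dimensional transect from
    2-D coordinates via an interpolated 0.5 hybrid-index contour, fitting of
    sigmoid geographic clines with optional exponential introgression tails to
    binned allele frequencies and quantitative traits by Metropolis-Hastings
    MCMC with AIC model selection, comparison of cline centers and widths
    through 2-log-likelihood support intervals, inference of hybrid classes
    from hybrid index and interclass heterozygosity using in-silico crosses,
    and binomial models of pollinator host choice. Includes a synthetic
    hybrid-zone generator with known ground truth for calibration and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    mgcv,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
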