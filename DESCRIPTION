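Package: geoherd
Title: Genomic Prediction with Spatially Correlated Herd Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) for livestock
    populations in which herd effects are modelled as spatially correlated
    random effects. Farm GPS coordinates are turned into a herd covariance
    kernel (standardized geodesic distances or a Matern covariance), variance
    components are estimated by average-information REML, and models with
    independent versus correlated herd effects are compared by replicated
    cross-validation (accuracy, reliability, heritability and
    environmentability), Tukey multiple comparisons, and an
    eigenstructure-based confounding diagnostic between the genomic and herd
    covariance structures. A synthetic-data generator reproduces the assumed
    statistical structure (HWE genotypes, skewed farm sizes, spatially
    correlated herd effects) for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
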