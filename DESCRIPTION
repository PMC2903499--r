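Package: grmvc
Title: Variance Components and SNP Model Selection with Pedigree and
    Genomic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Disentangles genetic from shared-environment (family and
    cage) variance in full-sib structured populations.  Builds pedigree
    numerator relationship matrices and SNP-based realized relationship
    matrices, estimates variance components by average-information REML,
    selects individual additive and dominance SNP effects by
    reversible-jump MCMC conditional on REML variance components,
    estimates intra-class correlations of relatives by independent-pair
    sampling, and validates models by within- and across-family
    cross-validation of phenotype predictions.  Includes a synthetic
    heterogeneous-stock data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
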