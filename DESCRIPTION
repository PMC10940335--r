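Package: gxevc
Title: Genotype-by-Environment Variance Components for Quantitative Traits
    in Extended Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood variance-components analysis of
    genotype-by-environment (GxE) interaction along a continuous
    environmental index (standardized socioeconomic status) in extended
    pedigrees.  Additive genetic, household and residual environmental
    variances are modelled as exponential functions of the environment,
    and genetic and household correlations as exponential-decay functions
    of pairwise environmental differences.  Provides recursive kinship
    computation from pedigree files, trait preprocessing (covariate
    residualization and rank-based inverse normalization), family-blocked
    multivariate-normal likelihood fitting with boundary-aware
    likelihood-ratio tests in a three-stage gatekeeping procedure, and a
    synthetic pedigree/phenotype generator for validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
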