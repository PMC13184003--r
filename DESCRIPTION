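Package: famliab
Title: Familial Liability Models for Register-Based Comorbidity Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying familial co-aggregation and the genetic
    architecture of comorbidity from national-register style data. Provides a
    synthetic multigenerational registry simulator built on a liability
    threshold ACE model with gene dropping; cohort construction, lifetime
    phenotype ascertainment and relative-pair enumeration from register
    tables; logistic models with cluster-robust sandwich variance for
    within-individual and between-relative odds ratios; tetrachoric
    correlation estimation from binary trait pairs; and weighted least squares
    fitting of univariate and bivariate (correlated factors) ACE models over
    full and half-sibling correlations, with delta-method confidence
    intervals for genetic correlations and bivariate variance decompositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
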