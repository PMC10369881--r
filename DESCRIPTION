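Package: igeq
Title: Indirect Genetic Effects and Heritability Under Assortative Mating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Theory and estimation for phenotypes shaped by direct genetic
    effects (DGEs) and parental indirect genetic effects (IGEs, 'genetic
    nurture') under assortative mating (AM) at equilibrium. Provides the
    equilibrium phenotypic-variance decomposition generalizing the
    Crow-Felsenstein single-factor inflation to correlated DGE and IGE
    components; closed-form expected coefficients for one- and two-generation
    polygenic-index (PGI) regressions under random mating and at equilibrium;
    a non-linear estimating-equation pipeline that maps two-generation PGI
    regression results plus a family-based heritability estimate to the
    equilibrium heritability, the correlation between parents' DGE components,
    and the variance contributed by IGEs, with delta-method standard errors;
    individual-level trio/sibling regression with family-clustered covariance;
    and a forward-in-time diploid simulator of assortative mating used to
    validate the pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    sandwich,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
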