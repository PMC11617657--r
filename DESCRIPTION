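Package: scentselect
Title: Plasticity and Natural Selection on Floral Volatile Emissions
Version: 0.9.0
Authors@R:
    person("Maxfield", "Meadow", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how floral volatile emissions and other
    floral traits respond to snowmelt-timing and summer-precipitation
    manipulations, and how phenotypic selection on those traits shifts with
    the environment. Covers GC-MS peak-table filtering and calibration-based
    quantitation of per-flower emission rates, constrained ordination
    (canonical analysis of principal coordinates) on Bray-Curtis distances
    with sequential permutation tests, split-plot linear mixed models with
    estimated marginal means, construction of four female-fitness measures
    with field imputation rules, selection-gradient estimation by class-level
    models, univariate trait-by-environment models and elastic-net
    regularized direct gradients, and classification of plastic responses as
    adaptive, maladaptive or neutral. A synthetic split-plot field-study
    generator with known truth parameters makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmnet,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
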