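Package: eimm
Title: Eco-Intersectional Multilevel (MAIHDA) Models for Area-Level
    Exposure Inequalities
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for eco-intersectional multilevel (EIM) analysis, the
    ecological form of MAIHDA (Multilevel Analysis of Individual
    Heterogeneity and Discriminatory Accuracy) in which small areas are
    nested within intersectional strata defined by cross-classified
    area-level characteristics.  Provides stratum construction from
    continuous covariates (fixed-proportion splits, quantile splits,
    thresholds), exact maximum-likelihood estimation of the two-level
    Gaussian random-intercept model via the profiled marginal likelihood,
    empirical-Bayes (shrunken) stratum residuals with 95% intervals,
    variance partition coefficients (VPC), proportional change in
    variance (PCV), ranked stratum predictions, a seeded synthetic-data
    generator emulating a national small-area air-pollution study, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
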