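Package: dalytraj
Title: Chronic-Disease DALY Trajectories with Hierarchical Growth-Curve Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cohort and socioeconomic disparities in the
    chronic-disease burden of middle-aged and older adults measured in
    disability-adjusted life years (DALYs, equated with years lived with
    disability for chronic non-fatal conditions). Provides a 13-disease
    disability-weight registry and duration-based YLD scoring, covariate
    coding for birth cohort, cohort-median age centering and socioeconomic
    status, a two-level quadratic growth-curve (linear mixed) model with
    cross-level cohort-by-SES interactions estimated by profiled maximum
    likelihood, chained-equation multiple imputation with Rubin's-rules
    pooling, predicted trajectory grids, and a synthetic longitudinal panel
    generator emulating a CHARLS-like four-wave survey for end-to-end and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
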