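Package: phnsmr
Title: Public Health Nurse Workforce and Small-Area Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal ecological analysis linking changes in the municipal
    public-health-nurse workforce to changes in mortality. Implements indirect
    age standardization, empirical Bayes smoothing of standardized mortality
    ratios under a Poisson-Gamma model with Marshall moment-estimated
    prefecture priors, first-difference linear mixed models with prefecture
    random intercepts, and a Besag-York-Mollie spatial Poisson model with an
    intrinsic conditional autoregressive component fitted by Markov chain
    Monte Carlo. Includes a synthetic municipality-panel generator with
    recorded ground truth so the whole pipeline is testable without external
    registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
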