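Package: dvcrisk
Title: Two-Stage Poisson Risk Modelling of Deer-Vehicle Collisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for model-based assessment of deer-vehicle collision
    (DVC) risk on the scale of administrative municipalities.  A mandatory
    parametric Poisson regression with log road length as offset captures
    road-type, survey-year and red-deer-district effects; deviations from
    this baseline are modelled by a component-wise boosted additive Poisson
    model with penalized spline, monotone spline, bivariate spatial,
    spatio-temporal and observation-level ridge base-learners.  The number
    of boosting iterations is chosen by out-of-bootstrap risk, relevant
    terms by stability selection.  The exponentiated nonparametric model
    part defines a multiplicative "DVC index" that decomposes into climate,
    land-use, browsing and spatial factors and can be classified into risk
    classes.  Browsing-survey proportions are smoothed over a district
    adjacency graph by an intrinsic conditional autoregressive (Markov
    random field) binomial model, and the index is validated externally
    against harvest densities via LOWESS trends and Spearman correlation.
    A synthetic-landscape generator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
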