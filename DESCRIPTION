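Package: mortsmooth
Title: Small-Area Space-Time Smoothing of Child Mortality from Survey Birth Histories
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Produces Admin-1 by period estimates of child mortality (5q0 for
    ages 0-4 and 10q5 for ages 5-14) from full-birth-history survey data.
    Implements design-based direct estimation via discrete-time survival
    analysis on person-month data with Taylor-linearization variances,
    inverse-variance pooling across overlapping surveys with optional HIV
    adjustment, a Bayesian space-time smoothing model (iid + RW2 temporal,
    iid + ICAR spatial, Knorr-Held type IV interaction) fitted by a conjugate
    Gibbs sampler, posterior coefficient-of-variation precision screening,
    draw-wise Pearson correlation between age groups with credible intervals,
    and variance decomposition of the fitted latent surface. Includes a
    synthetic-data generator emulating stratified two-stage cluster sampling
    with probability-proportional-to-size cluster selection over a known
    mortality surface, so the whole pipeline is testable against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
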