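Package: nestpower
Title: Simulation and Power Analysis for Two-Level Nested Experimental Designs
Version: 0.1.0
Authors@R:
    person("nestpower", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the consequences of cluster-related variation in
    nested (multilevel) experimental designs with two conditions. Generates
    synthetic data under random-intercept and random-intercept/random-slope
    linear mixed models, fits the competing analyses commonly applied to such
    data (t tests on individual observations, paired t tests on cluster
    summary means, fixed-effects dummy regression, and linear mixed models),
    and quantifies -- by Monte-Carlo experiment and in closed form -- the
    false-positive-rate inflation and power loss incurred when cluster-related
    variation in the intercept and/or the experimental effect is ignored.
    Includes analytic standard errors and power curves for planning the
    allocation of clusters versus observations per cluster, and a command-line
    interface for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
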