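Package: udlreach
Title: Planning and Execution Components of Use-Dependent Reaching Biases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing use-dependent biases in centre-out reaching
    into a reaction-time-dependent planning component and a small, stable
    execution component. Provides a two-process generative simulator of reach
    schedules, headings and 200 Hz stylus trajectories; trajectory kinematics
    (velocity-threshold onset detection, early heading angle, validity
    screening, baseline correction and bias recoding); a distributional core
    (one- and two-component Gaussian mixtures fit by EM, a parametric-bootstrap
    likelihood-ratio test of bimodality, and bootstrap confidence intervals for
    the heading-distribution peak near the probe target); reaction-time
    statistics (quintile binning, bias-versus-RT slopes, probe-distance
    contrasts, reward-group comparisons); and a deterministic end-to-end
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
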