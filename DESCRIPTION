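Package: hvarnet
Title: Hierarchical Bayesian Vector Autoregression for Multi-Subject
    Effective Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a hierarchical Bayesian vector autoregressive (VAR) model
    to multi-subject, multi-condition region-of-interest (ROI) time series,
    such as block-design fMRI experiments.  VAR coefficients switch with the
    experimental condition, subjects deviate from group-level coefficients
    through diagonal random effects, and an elastic-net-equivalent shrinkage
    prior controls the quadratically growing parameter space.  All unknowns
    are sampled by a Gibbs sampler with closed-form full conditionals.
    Posterior draws are turned into directed Granger-causality networks at
    the group, contrast (condition or group difference), and subject level
    via highest-density-region tests on lag-joint coefficient distributions,
    with summaries of between-subject connectivity variability.  Includes
    nuisance detrending (canonical HRF response, polynomial drift, seasonal
    components), a synthetic-study simulator with known ground truth, and
    plain-text readers and writers for every input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
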