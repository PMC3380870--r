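Package: nemhop
Title: Nested Effects Model Inference by EM and Mode-Hopping MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure learning for Nested Effects Models (NEMs) from
    gene-perturbation screens. Implements a closed-form
    Expectation-Maximization algorithm for the marginal structure
    posterior of the signals graph, a mode-hopping Metropolis-Hastings
    sampler over the EM local maxima, and an Empirical Bayes loop that
    re-estimates the effect-attachment prior from the sampled graphs.
    Includes a synthetic-screen generator with a two-valued alpha/beta
    log-odds noise model, baseline learners, benchmark utilities
    (edge sensitivity/specificity, prior distance, posterior quantile),
    and post-processing helpers (indistinguishable-node merging, effect
    grouping by attachment and direction, consensus over seeds).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
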