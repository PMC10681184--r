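Package: pcstroop
Title: Design, Simulation and Mixed-Model Analysis of Proportion-Congruency Spatial Stroop Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emotional-priming spatial Stroop experiments in which the
    proportion of congruent trials is manipulated simultaneously at the
    list-wide (LWPC) and item-specific (ISPC) level. Builds dual
    proportion-congruency block designs, pseudorandomizes trial order under
    run-length and first-order-priming constraints, computes trial-wise
    probability predictors (LWPC, ISPC, contingency, response and location
    probabilities) with a three-level binary Hierarchical Gaussian Filter,
    selects trial lists that decorrelate item-specific congruency from
    contingency, simulates reaction-time datasets from a crossed-random-effects
    generative model, applies the standard exclusion and inverse-RT
    preprocessing, fits linear mixed models with crossed participant and
    stimulus random effects (with backward elimination, residual-outlier refit
    and marginal/conditional R2), computes post-hoc slope and marginal-mean
    contrasts with Tukey adjustment, and performs power analysis for
    fully-crossed designs via variance partitioning coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
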