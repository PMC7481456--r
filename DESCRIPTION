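Package: telag
Title: Lagged Transfer Entropy for Directed Cardiorespiratory Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Directed, time-scale-resolved coupling analysis between two
    physiological time series with lagged Transfer Entropy. Implements
    non-uniform (greedy, significance-gated) embedding of past states,
    nearest-neighbor conditional mutual information estimation, time-shift
    surrogate significance testing, a coupled autoregressive validation
    system, a synthetic cardiorespiratory record generator, the
    heart-rate-variability preprocessing chain (artifact rejection,
    beat-aligned respiration resampling, fixed-length segment extraction),
    and the accompanying statistical designs (lag ANOVA with Bonferroni
    post hoc tests, covariate-adjusted cohort models, Sobel mediation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    car,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
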