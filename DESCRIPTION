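Package: sleeptopics
Title: Topic-Model Decomposition of Sleep EEG into Concurrent Vigilance States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analyzes polysomnography as a mixture of latent vigilance states.
    Multichannel sleep EEG/EOG is band-pass filtered, screened for artifacts,
    and symbolized into per-epoch distributions of 3-letter spectral "words"
    built from quantile-categorized 1-s band power. A six-topic Latent
    Dirichlet Allocation model (collapsed Gibbs sampling) expresses each 30-s
    epoch as a probability mixture over data-driven vigilance states, from
    which stable-epoch dominance, co-occurrence, and epoch-to-epoch transition
    statistics are derived. Includes a synthetic polysomnography generator
    with stage-dependent spectral profiles and an injectable light-sleep
    intrusion effect, plus cohort-level statistics (rank-sum tests,
    mixed-effects models, partial correlations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
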