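Package: visprior
Title: Bayesian Observer Modelling of Acquired Priors in Visual Motion Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generative observer models for visual statistical learning in a
    motion-direction estimation task. Implements a Bayesian observer in which a
    learned bimodal von Mises prior over motion directions is combined with a
    noisy sensory likelihood, read out as the posterior circular mean, and
    corrupted by motor noise and uniform lapses; also implements a family of
    non-Bayesian response-strategy models. Provides a synthetic-data generator
    emulating the task's trial schedule and adaptive contrast staircases,
    maximum-likelihood fitting with a motor pre-fit and multi-start simplex
    search, BIC-based random-effects model comparison, behavioral statistics
    for estimation bias, variability and no-stimulus hallucinations, a
    parameter-recovery experiment, and robust (Huber IRLS) and Kendall tau-b
    trait-correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
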