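Package: stressmeta
Title: Stress Reactivity and Metacognitive Sensitivity: Simulation and
    Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("stressmeta", "authors", role = c("aut", "cre"),
           email = "maintainer@stressmeta.invalid")
Description: Tools for studying how biological stress reactivity relates to
    metacognitive accuracy in perceptual decision tasks. Implements a
    signal-detection observer model for two-interval forced-choice (2IFC)
    trials with confidence ratings, 1-up 2-down interleaved adaptive
    staircase calibration, model-free metacognitive sensitivity via the
    area under the type-2 ROC curve, cortisol-based stress-reactivity
    screening, windowed heart-rate-variability analysis with bootstrap
    cluster inference, and the group-level statistical stage (one-way and
    mixed ANOVA with effect sizes, Bonferroni post-hocs, and regression of
    metacognitive sensitivity on cortisol reactivity). A synthetic-cohort
    generator reproduces the statistical structure the analysis assumes so
    the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
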