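Package: multiword
Title: Design, Models, and Analysis for Multi-Word Reading fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simultaneous-suppression experiments on visual word
    recognition: a counterbalanced trial-design generator with word-list
    balancing, evidence-accumulation models (serial, limited- and
    unlimited-capacity parallel, and hybrid parallel-then-serial) that predict
    BOLD responses as the integral of activation over time, a velocity-threshold
    eye-tracking quality-control pipeline (drift correction, blink, saccade, and
    fixation-break detection), single-trial linear mixed-effects analyses with
    planned contrasts and FDR correction, simulation-based power analysis for
    paired designs, and synthetic-data generators with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
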