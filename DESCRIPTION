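Package: tempshift
Title: Temporal-Shift Detection Experiments: Stimuli, Staircases and
    Signal Detection Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditory temporal-shift detection experiments with
    rhythmic quintet sequences. Synthesizes narrowband (4-ERB) carrier
    sounds and quintet stimuli, builds periodic, aperiodic and temporally
    cued trial sequences with counterbalanced session plans, runs
    2-down-1-up adaptive staircases, simulates an equal-variance Gaussian
    signal-detection observer with condition-dependent sensitivity and
    log-normal reaction times, and analyzes trial logs with classical and
    probit-GLM d-prime estimation (including a Laplace-approximated
    subject random intercept), planned contrasts with Bonferroni
    correction, likelihood-ratio tests, subject-level bootstrap
    confidence intervals and correct-trial log reaction-time summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
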