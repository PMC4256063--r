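Package: eqnoise
Title: Simulation and Analysis of Rapid Equivalent-Noise and Motion-Coherence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing rapid equivalent-noise and
    motion-coherence direction-discrimination experiments of the kind used to
    study the development of global motion perception. Provides random-dot
    kinematogram stimulus generation (wrapped-normal and coherence-mixture
    direction fields), generative observer models with known internal noise,
    effective sampling and lapse rate, a QUEST Bayesian adaptive staircase
    engine with interleaving and catch trials, the equivalent-noise
    decomposition of thresholds into internal noise and sampling (including a
    Monte Carlo re-derivation of the maximum-tolerable-noise mapping and an
    ideal-observer lapse correction), a synthetic developmental-cohort
    generator, and the group-level statistical pipeline (catch-trial
    screening, log transforms and outlier rules, developmental trajectory
    fits, hierarchical stepwise regression, and fixation-stability analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
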