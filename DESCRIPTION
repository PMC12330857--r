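Package: vigifc
Title: Vigilance-Dependent Seed-Based Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the functional connectivity of small
    subcortical seed regions changes with vigilance state (alertness and
    drowsiness) in resting-state fMRI. Provides EEG band-power vigilance
    staging with a signed-rank epoch classifier, respiratory-volume and
    heart-rate extraction from peripheral recordings, pupillometry-based
    percent eye closure, Legendre detrending and zero-phase band-pass
    filtering, three confound-regression pipelines (tissue means, anatomical
    CompCor, and convolved physiological response functions), static and
    state-conditioned seed correlation maps with Fisher r-to-z transform,
    random-intercept linear mixed-effects group inference fitted by REML,
    dual t-map thresholding with false-discovery-rate control, signed-map
    reproducibility statistics (multiclass Dice and signed overlap
    coefficients), sliding-window dynamic connectivity with city-block
    k-medians state clustering, and a multi-subject synthetic-study
    generator with planted state-dependent effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
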