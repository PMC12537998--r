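Package: flowprobe
Title: Auditory Oddball ERP Analysis and Workload-State Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-task auditory oddball EEG studies of
    mental workload and flow. Provides a synthetic 32-channel oddball EEG
    generator, a continuous-to-clean-epochs preprocessing chain (detrending,
    zero-phase Butterworth band-pass, epoching, SD-threshold channel and epoch
    rejection, FASTER-style component metrics, baseline correction), spherical
    spline channel interpolation and surface Laplacian current source density,
    mass-univariate spatiotemporal cluster permutation statistics
    (repeated-measures F and paired t), time-resolved multivariate decoding
    with Ledoit-Wolf shrinkage LDA, stratified dummy baselines, bootstrap
    confidence-interval inference and Haufe activation-pattern
    transformation, and behavioral statistics (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Tukey HSD post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
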