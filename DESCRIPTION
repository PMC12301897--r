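Package: eegbrainage
Title: EEG Brain-Age Decoding and State-vs-Trait Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decodes brain age from multichannel clinical EEG with a temporal
    convolutional regressor trained by cropped decoding, corrects the
    age-dependent prediction bias with a quadratic model, and evaluates the
    resulting brain-age gap as a pathology biomarker. Includes a synthetic
    clinical-EEG cohort generator with planted trait and state gap components,
    longitudinal dataset derivatives (repeated and transition cohorts),
    two-threshold biomarker optimisation, change-rate and moment-of-transition
    statistics, permutation tests, and amplitude-gradient saliency maps per
    channel and frequency band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
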