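Package: spindlecwt
Title: Sleep Spindle Detection by Continuous Wavelet Transform with
    Individually Adjusted Frequency Bands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects sleep spindles in polysomnographic EEG using a complex
    Morlet continuous wavelet transform with amplitude-adaptive detection
    thresholds, automatic rejection of muscle-artifact and alpha-dominated
    segments, and individual adjustment of slow and fast spindle frequency
    ranges from frontal versus parietal channels. Includes scorer-agreement
    statistics on binarized spindle timelines (Cohen's kappa, Matthews
    correlation, adjusted G-mean), classical twin-study genetic variance
    analysis with within-pair and combined estimators, bootstrap
    significance thresholds for intraclass correlations, and a synthetic
    EEG and twin-phenotype generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
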