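Package: apneatw
Title: Sleep Apnea Detection from Single-Lead ECG with a Time-Window Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep apnea from single-lead electrocardiogram recordings
    one minute at a time. Implements the full pipeline: FIR bandpass denoising,
    Hamilton-style adaptive R-peak detection, median-filter RR correction,
    eighteen heart-rate-variability and ECG-derived-respiration features per
    one-minute segment, a one-hidden-layer perceptron whose input concatenates
    a moving window of consecutive segments (hidden width 2M+1), and
    recording-level diagnosis via the apnea-hypopnea index. Ships a synthetic
    apnea-ECG generator with known ground truth so the whole pipeline is
    testable offline, plus evaluation harnesses (window-size sweep,
    recording-level k-fold cross-validation, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
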