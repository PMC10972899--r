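Package: crawlr
Title: EMG-Based Pattern Recognition of Inter-Limb Coordination in Human Crawling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying inter-limb coordination modes
    (ILCMs) in human hands-knees crawling from multi-channel surface EMG.
    Provides the eight-mode ILCM catalogue with ideal limb-timing schedules,
    ipsilateral phase lag (IPL) and duty-factor gait metrics, crawling-cycle
    segmentation from a palm pressure signal via its first derivative, EMG
    envelope feature extraction (high-pass, demean, rectify, low-pass, unit
    variance, 1000-point cycle normalization), three classifiers (a
    from-scratch bidirectional LSTM, SVM, KNN), three evaluation protocols
    (participant-specific, multi-participant, participant-independent), and a
    synthetic cohort generator that emulates the statistical structure of
    crawling recordings so the whole pipeline is testable without any
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    Rtsne,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
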