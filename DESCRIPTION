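Package: oxiscreen
Title: Screening for Moderate-to-Severe Sleep Apnea from Overnight Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of overnight 1-Hz pulse-oximetry (SpO2)
    recordings as an abbreviated screening test for moderate-to-severe
    obstructive sleep apnea. Provides artifact removal and gap bridging for
    portable oximetry, extraction of 16 oximetric features (time- and
    frequency-domain statistical moments, spectral measures in the
    0.014-0.033 Hz apnea band, sample entropy, central tendency measure and
    Lempel-Ziv complexity), fast correlation-based filtering by symmetrical
    uncertainty, a regression multilayer perceptron with weight decay that
    estimates the apnea-hypopnea index (AHI), conventional oxygen
    desaturation indices (ODI3/ODI4, CT90, basal/min/mean SpO2), and a full
    agreement and diagnostic-performance evaluation layer (intraclass
    correlation, Bland-Altman, mountain plots, ROC/AUC, sensitivity,
    specificity, predictive values and likelihood ratios with confidence
    intervals). A synthetic-recording simulator with known ground truth
    supports end-to-end validation without patient data.
License: MIT
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
    withr,
    nnet,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
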