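Package: sodquant
Title: Image Quantification and Censored Statistics for Preclinical ALS
    Efficacy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements the quantitative machinery of a SOD1-G93A mouse
    efficacy study as a tested pipeline: automated DAB-immunohistochemistry
    quantification (motor-neuron counting by threshold/reconstruction/
    watershed, positive-pixel stain area with a minimum cluster-size cutoff),
    rule-based derivation of longitudinal disease endpoints (two-consecutive
    symptom onset, sustained weight-loss onset, last full wire hang, humane
    euthanasia criteria, censoring classification), and censored two-sample
    statistics including a combined max(Wilcoxon, log-rank) permutation test,
    Kaplan-Meier summaries, Weibull likelihood-ratio survival comparison and
    mixed models for balance-beam trials. Ground-truthed synthetic histology
    images and a simulated two-arm cohort make every step testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    survival,
    lme4,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
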