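Package: sudepmetrics
Title: Longitudinal Biomarker Quantification for Preclinical SUDEP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temporal biomarkers of sudden unexpected death in
    epilepsy (SUDEP) from longitudinal multimodal mouse physiology: seizure
    burden from annotated events, EEG/EMG sleep staging by band power and
    principal components, operational bradycardia from ECG segment mean heart
    rates, apnea detection from whole-body airflow traces, and pulse-oximetry
    quality control with hypoxemia demarcation. Endpoints are retrospectively
    realigned to the day of sudden death ('days prior to death') and pooled
    into 10-day bins; cohorts (genotype by diet) are compared with
    Kaplan-Meier/log-rank survival analysis and a battery of factorial tests.
    A seeded synthetic-study generator reproduces the reported cohort-level
    statistical structure so the whole pipeline is exercisable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    car,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
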