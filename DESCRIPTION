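Package: oedrisk
Title: Projected Secondary-Cancer Risk from Dose-Volume Histograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organ-equivalent-dose (OED) modelling of radiation-induced
    secondary-malignancy risk after breast radiotherapy. Reads per-organ
    dose-volume histograms (DVHs), converts between cumulative and
    differential form, evaluates linear, linear-exponential (cell-killing)
    and plateau dose-response kernels, projects excess absolute risk (EAR)
    per 10,000 person-years from organ-specific risk coefficients, adds
    cone-beam CT image-guidance dose as organ-level uniform increments, and
    compares treatment cohorts (partial vs whole breast irradiation, MR-linac
    vs conventional linac) with Welch t-tests and uncapped Bonferroni
    correction. Includes a seeded synthetic DVH cohort generator calibrated
    to published group summaries for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
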