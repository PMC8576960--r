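Package: pafscreen
Title: Paroxysmal Atrial Fibrillation Screening from Non-Episode ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Early screening of paroxysmal atrial fibrillation (PAF) from
    single-lead ECG recorded away from any episode. Extracts six P-wave
    morphology parameters (width, amplitude, onset-to-peak time, and the
    A/C/W parameters of a Gaussian wave model fitted by a hybrid
    Taguchi-genetic algorithm) together with 25 heart-rate-variability
    parameters (time-domain, Welch/autoregressive frequency-domain, and
    nonlinear: Poincare SD1/SD2, approximate and sample entropy, detrended
    fluctuation analysis), then classifies subjects with Bagging, AdaBoost,
    and two-layer Stacking ensembles of CART trees evaluated by stratified
    tenfold cross-validation. Includes a seeded synthetic ECG cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    rpart,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
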