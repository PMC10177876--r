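Package: mucospec
Title: Diffuse Reflectance Spectroscopy Analysis for Oral Mucosa Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage analysis pipeline for diffuse reflectance spectroscopy
    (DRS) of the oral mucosa. Stage one selects informative wavelength subranges
    with a per-wavelength class-separability statistic (the Q coefficient),
    converts spectra to band-area features, and benchmarks a panel of
    classifiers under stratified cross-validation, reporting class-conditional
    confusion frequencies, sensitivity, and specificity. Stage two implements a
    patient-individual procedure: a bootstrap reference spectrum of the intact
    area, joint maximum normalization of the intact/lesion/reference triple,
    difference (delta) spectra, and patient-grouped classification over a grid
    of wavelength ranges. A synthetic tissue-optics generator produces cohorts
    of backscattering spectra with hemoglobin/water absorption bands,
    wavelength-dependent scattering, fluorescence background, per-patient gain
    variability, and measurement noise, so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
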