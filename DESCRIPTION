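Package: meatspec
Title: Chemometric Meat Speciation and Halal Screening for Handheld
    Vis-NIR and NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating meat species from handheld visible/
    near-infrared (Vis-NIR, 400-1000 nm) and near-infrared (NIR, 900-1700 nm)
    reflectance spectra. Provides a catalogue of spectral pre-processing
    operators (SNV, MSC/EMSC, Savitzky-Golay and gap-segment derivatives,
    orthogonal signal correction, wavelet features), replicate-aware sample
    set partitioning (duplex, Kennard-Stone, random) and cross-validation
    schemes (venetian blinds, leave-one-out, random subsets), a one-class
    screening engine for "not pork meat" flagging (SIMCA, kNN distance, PCA
    residual, Mahalanobis, one-class SVM with AUROC screening, class-limit
    scenarios and 2-of-3 ensemble voting), four-species discriminant models
    (PLS-DA with VIP selection, kernel SVM) with leave-class-out validation,
    and a synthetic spectra generator emulating dual-sensor acquisition
    campaigns so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
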