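Package: lungdens
Title: Quantitative CT Lung Densitometry for Expiratory Air-Trapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes paired inspiratory/expiratory lung-density indices
    (mean lung density, expiratory-to-inspiratory ratios, Hounsfield-unit
    threshold attenuation fractions) from 3-D CT volumes with lung masks,
    and evaluates them as diagnostic markers for bronchiolitis obliterans
    via Mann-Whitney group comparison, age/sex-adjusted linear and logistic
    regression, and ROC analysis with Youden-optimal cutoffs. Includes a
    synthetic paired-phase chest phantom generator with closed-form expected
    index values and a cohort-table simulator calibrated to published group
    summaries, so the whole pipeline runs and is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
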