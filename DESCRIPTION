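Package: ctdnaITH
Title: Spatial and Temporal Intra-Tumoural Heterogeneity from Multi-Region
    Tumour and Serial Plasma Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-region tumour (core and advancing
    margin) and serial plasma cell-free DNA sequencing in head and neck
    squamous cell carcinoma. Starting from per-patient multi-sample variant
    calls, the package applies a germline/CHIP subtraction cascade with
    COSMIC-driver rescue rules, quantifies spatial intra-tumoural
    heterogeneity as tumour sub-site exclusivity, measures concordance
    between baseline circulating tumour DNA and tumour variants, and tracks
    baseline versus acquired variants across post-treatment plasma
    timepoints to call molecular recurrence ahead of clinical detection.
    A forward simulator of clonal tumours with plasma shedding generates
    pipeline-ready cohorts with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
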