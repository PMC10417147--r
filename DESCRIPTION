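Package: cbctsct
Title: CBCT-Based Synthetic CTs and Adaptive Proton Therapy Triggers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic computed tomography images from cone-beam CT
    (CBCT) for dose monitoring in head-and-neck proton therapy: a corrected
    CBCT built by iterative joint-histogram piecewise-linear intensity
    conversion plus low-frequency artifact correction, a virtual CT built by
    deformable registration of the planning CT with low-density masking, and
    a ground-truth CT built from a same-day verification CT. Includes a
    head-and-neck phantom simulator (anatomical change, CBCT degradations),
    deformable image registration, a simplified spread-out-Bragg-peak proton
    dose proxy with water-equivalent path-length ray tracing, dose-volume
    histogram D99 coverage metrics, and the D99-based adaptive-planning
    trigger workflow with cohort accuracy statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
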