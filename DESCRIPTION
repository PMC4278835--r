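Package: lvphase
Title: Automatic Left-Ventricle Phase Detection for 4D Cardiac CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the cardiac phase with high left-ventricle and low
    right-ventricle contrast in a dynamic (4D) cardiac computed tomography
    acquisition, using the time-dependent distribution of contrast agent.
    Each voxel eligible in the first phase (30-150 Hounsfield units) votes
    for the phase at which its attenuation peaks, provided the peak shows a
    sufficient increase over the first phase; the phase with the most votes
    is selected. Includes an integer-factor mean-pooling shrink filter that
    trades resolution for speed, a seedable synthetic first-pass contrast
    phantom with known ground truth for validation, exact Clopper-Pearson
    binomial confidence intervals for reader-agreement ratios, and readers
    and writers for NIfTI-1 and MetaImage volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
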