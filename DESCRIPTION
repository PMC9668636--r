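Package: rishnet
Title: Multi-Site Harmonization and Thresholding of Diffusion MRI Structural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for multicentre diffusion-MRI structural connectome analysis:
    group connection-probability and FA-weighted matrices, cross-site consistency
    via the relative-difference statistic, fixed-density network thresholding,
    harmonization of the diffusion signal across scanners with rotation-invariant
    spherical-harmonic (RISH) features, covariate-adjusted edgewise permutation
    statistics with effect-size gating and FDR correction, and precision and
    sensitivity scoring of detected disease-affected connections against a
    reference edge set. Includes a synthetic multi-site cohort and diffusion-signal
    phantom generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
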