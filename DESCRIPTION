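Package: fcclean
Title: Benchmarking Data-Driven Artifact Removal for Resting-State fMRI
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-group resting-state fMRI cohorts with known
    network structure, a planted default-mode-network connectivity deficit,
    and realistic artifact sources (motion, CSF pulsation, white-matter
    drift, vessel signal, scanner drift), and benchmarks four data-driven
    cleanup strategies (24-parameter motion regression; motion plus mean
    WM/CSF regression; ICA-based soft and aggressive component removal)
    against uncleaned data. Provides seed-based and template-based
    dual-regression connectivity mapping, temporal-SNR and fluctuation
    suppression metrics, within-group consistency maps, and between-group
    inference by ROI t-tests and permutation GLM with cluster-extent
    correction and a gray-matter-volume covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
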