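Package: llrpipe
Title: Stretch-Evoked Long-Latency Reflex Analysis for Simultaneous EMG and fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stretch-evoked long-latency reflex (LLR)
    activity recorded simultaneously with functional MRI. Implements adaptive
    noise cancellation of motion artifacts in EMG via a Takagi-Sugeno fuzzy
    inference system trained with hybrid least-squares/gradient learning,
    LLR amplitude quantification from rectified EMG envelopes, agreement
    statistics (paired Bland-Altman, Jaccard overlap of limits of agreement
    with bootstrap confidence intervals, perturbation-level z-scores, Bartlett
    variance tests), voxelwise general linear models of BOLD signal with
    muscle-specific amplitude-modulated regressors, and test-retest
    reliability metrics (Sorensen-Dice overlap, ICC(3,1)). A synthetic-data
    module generates perturbation protocols, EMG recordings with known clean
    signal and motion artifacts, and BOLD phantoms with known effect maps, so
    the entire pipeline is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
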