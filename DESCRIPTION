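Package: narranet
Title: Modality-Invariant Narrative Brain Networks from Two-Condition fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating narrative-driven functional brain networks that
    respond similarly to the same story presented in two different media (an
    audiovisual movie and its written script). Implements temporal-concatenation
    group spatial independent component analysis with an InfoMax unmixing core,
    GICA3-style back-reconstruction of subject- and condition-level maps and
    time-courses, percent-signal-change scaling, cross-modal component rankings
    ("correlation over averages" and "average over correlations") with circular
    shift-permutation inference and Benjamini-Hochberg adjustment, an
    HRF-convolved dialog-regressor correlation analysis, framewise-displacement
    and DVARS quality control, Gaussian smoothing and discrete-cosine high-pass
    filtering, group one-sample t-maps with cluster-extent thresholding and
    atlas-based cluster labelling, and a ground-truthed synthetic two-condition
    BOLD data generator for validating the whole pipeline.
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
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
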