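Package: captionbrain
Title: Caption-Embedding Models of Visually Evoked Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating sentence-embedding representations of scene
    captions to visually evoked fMRI responses: representational similarity
    analysis (RSA) with subset sampling, searchlight machinery and
    leave-one-participant-out noise ceilings; voxelwise encoding and
    brain-to-embedding decoding via fractional ridge regression with
    cross-validated per-target regularization; dictionary-lookup caption
    retrieval with rank summaries; control feature models (multi-hot
    categories, averaged word vectors, part-of-speech-filtered features);
    noise-ceiling-corrected model comparison with Benjamini-Hochberg group
    inference; and a synthetic multi-participant cohort generator with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
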