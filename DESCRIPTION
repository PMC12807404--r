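Package: cogtraj
Title: Longitudinal Multimodal Modeling of Cognitive Decline from Spontaneous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects early cognitive decline (mild cognitive impairment) from
    longitudinal spontaneous-speech interviews. Extracts pause, utterance-length
    and part-of-speech features from timed transcripts and clip-pooled frame
    features from audio, fuses the two modalities into per-story embeddings, and
    models per-subject aging trajectories with a cross-attention module and
    direction embeddings trained under subject- and group-alignment contrastive
    losses. Includes subject-wise cross-validated training with soft voting,
    trajectory visualization by principal components, and a synthetic
    longitudinal cohort generator so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
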