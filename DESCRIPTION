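Package: mindyr
Title: Conditional Mutual Information Inference of Transcription Factor Modulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers post-transcriptional modulators of transcription factor
    (TF) activity from expression cohorts by conditional mutual information
    (the MINDy approach). Derives TF regulons from a genes-by-samples
    expression matrix, stratifies samples into tertiles by each candidate
    modulator's expression, recomputes TF-target mutual information within
    the modulator-high and modulator-low strata, and scores each target by
    the normalised differential mutual information (dMI) with permutation
    significance and bootstrap stability. Regulon-level modulation is tested
    with Fisher's exact and Kolmogorov-Smirnov statistics, modulators are
    classified as positive or negative, "in-modulators" (targets of one TF
    that modulate another) are enumerated, and two-cohort consensus calls
    are supported. Includes a synthetic-cohort generator with planted,
    modulator-dependent couplings for validation, and an empirical
    gene-set resampling test for aberration-frequency enrichment.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
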