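Package: erpspell
Title: Simulation and Decoding of ERP Matrix-Speller Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for offline P300 matrix-speller studies: stimulus-schedule
    generation for row-column and random-set presentation paradigms (with and
    without face overlays), a forward model that simulates multichannel EEG with
    class-dependent P300/N170/N400f components over 1/f background activity,
    standard ERP preprocessing (zero-phase band-pass filtering, anti-aliased
    decimation, epoching, baseline correction), signed-r2 discriminative interval
    selection, shrinkage-regularized linear discriminant analysis, letter decoding
    by evidence accumulation, information transfer rates, chronological
    cross-validation, and the accompanying statistics (sign tests, repeated
    measures ANOVA, target-to-target interval profiles, error topographies).
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
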