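Package: partseq
Title: Segmentation and Statistical Structure of Iterated Sequence-Learning Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transmission-chain (iterated learning)
    experiments in which sets of colour sequences are copied from one
    generation of learners to the next. Implements trigram
    transitional-probability estimation, boundary detection at relative
    dips in transitional probability calibrated against random baseline
    sets, unit ("lexicon") inventories, emergence diagnostics (unit
    length, within- versus between-unit transitional probabilities,
    Zipfian rank-frequency fit, Shannon entropy, normalised Levenshtein
    copying error), linear mixed-effects generation-trend models, and a
    synthetic-data module (random baselines, planted-lexicon generators,
    and a chunk-based agent simulator) so the full pipeline can be run
    and validated without external data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
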