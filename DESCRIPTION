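Package: dreamcomplexity
Title: EEG Complexity Measures and Dream-Report Analysis for Serial-Awakening Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether EEG complexity tracks the presence of
    dream experience during deep sedation. Implements single-channel
    Lempel-Ziv complexity (LZc) of spontaneous EEG via analytic-signal
    envelope binarization with shuffle normalization, the state-transition
    perturbational complexity index (PCIst) for TMS-evoked trial sets, a
    three-class scheme for classifying awakening reports, and the matching
    statistical layer (random-intercept linear mixed models with Type-III
    tests and estimated marginal means, matched-pairs Wilcoxon signed-rank
    tests, Holm-Bonferroni correction, IQR outlier screening). A synthetic
    EEG cohort generator emulating wake and sedation state profiles makes
    the full pipeline runnable and testable without any recordings.
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
    emmeans,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
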