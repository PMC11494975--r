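Package: neuromove
Title: Brain-Movement Coupling Analysis for Upper-Limb Functional Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synchronized brain-movement recordings during
    upper-limb functional tasks (paced reaching and circular steering) in healthy
    and post-stroke cohorts. Computes trunk-compensation kinematics and
    proximal-arm non-use, steering-law effective index of performance, fNIRS
    oxy-hemoglobin responses via the modified Beer-Lambert law with block
    averaging, and EEG alpha/beta event-related (de)synchronization from
    event-related spectral perturbation maps. Includes a synthetic multimodal
    session and cohort generator with ground truth for validation, and the
    statistical layer used to relate brain and movement measures: mixed ANOVA
    with partial eta-squared, Benjamini-Hochberg-corrected pairwise post-hocs,
    and Spearman rank (partial) correlations.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
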