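Package: lungesym
Title: Movement Asymmetry Analysis for Horses Trotting on the Lunge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative gait-analysis pipeline for upper-body movement
    asymmetry in trotting horses assessed in hand and on the lunge. Converts
    tri-axial inertial sensor recordings from five body landmarks (poll,
    withers, sacrum, left and right tuber coxae) into vertical displacement by
    frame rotation and drift-corrected double integration, segments strides,
    and computes eleven movement asymmetry indices (HDmin, HDmax, HDup, WDmin,
    WDmax, WDup, PDmin, PDmax, PDup, HHD, RD) per assessment condition.
    Implements sign normalization against preexisting straight-line asymmetry,
    inside/outside rein relabeling, average-rein combination, Bland-Altman
    limits of agreement, straight-line versus rein trend fits, and
    random-intercept mixed models with balanced-grid estimated marginal means
    and Bonferroni-adjusted pairwise comparisons. Includes a synthetic
    trotting-horse signal and study generator with controllable asymmetry,
    circle-induced body lean, and horse-level random effects, so the whole
    chain is testable without instrumented horses.
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
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    emmeans,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
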