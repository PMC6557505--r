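Package: sevtools
Title: Quantitative Erythema Assessment from Calibrated Skin Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for objective measurement of skin erythema, in particular
    radiation-induced dermatitis, from calibrated digital photographs. The
    pipeline converts sRGB images to the CIELAB color space, applies an
    affine color correction fitted from a photographed reference card,
    summarizes L*, a*, b* over masked measurement areas, and computes the
    per-pixel Standard Erythema Value SEV = (L*max - L*) x a* together with
    the baseline-subtracted Delta-SEV that is insensitive to individual skin
    tone. Cohort-level statistics (chi-square tests on contingency tables,
    two-sample t-tests from summary statistics, one-way ANOVA with
    Tukey-Kramer post-hoc comparisons, inter-observer grade comparison) and
    a fully seeded synthetic-data generator for skin images and patient
    cohorts are included.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
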