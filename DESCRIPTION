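Package: motorpool
Title: Scatter-Index Morphometry of Spinal Motor Pools from Serial Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the topographic organization of retrogradely labeled
    spinal motor pools reconstructed from serial coronal sections. Serial
    sections are aligned by a least-squares rigid fit to four optical
    reference points, rescaled to normalized hemicord units via a spline-
    smoothed lateral-edge intercept profile (correcting the diameter increase
    at the cervical enlargement), and projected along the anterior-posterior
    axis. Pool spreading is summarized by a covariance-ellipse scatter index
    (pi times the product of the covariance eigenvalues) and directional
    standard deviations. Includes a synthetic cohort generator with
    ground-truth parameters (anatomy, ladder-rung behavior, synapse counts,
    perineuronal-net categories) and the accompanying statistical layer:
    normality-gated two-group tests, two-way repeated-measures ANOVA
    interaction tests, scatter-vs-performance regression, and category and
    count comparisons.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
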