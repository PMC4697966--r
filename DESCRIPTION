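Package: humerometry
Title: Regional Histomorphometry of the Proximal Humerus on Frontal Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible regional histomorphometry of 2D frontal sections of
    the proximal humerus. Builds the geometric landmark system (humeral long
    axis, anatomical-neck chord, and derived construction lines) on calibrated
    binary bone/cartilage masks, partitions the cancellous bone into head,
    subcapital, medial metaphyseal, and subchondral/inner regions, measures
    trabecular bone area fraction (BV/TV), subchondral plate thickness along
    radial rays, and medial/lateral cortical thickness along periosteal
    normals, allocates donors to WHO T-score groups, and runs a
    normality-gated parametric/nonparametric comparison workflow with
    Bonferroni correction. Ships a seeded synthetic-section generator with
    known ground truth so the whole pipeline is testable without specimen
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
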