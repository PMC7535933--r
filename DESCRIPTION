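Package: centrodyn
Title: Quantifying Centriole Dynamics in Developing Hair Cells from 3D
    Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for quantifying mother and daughter centriole
    movements during hair-bundle polarity acquisition in inner-ear hair
    cells. Simulates two-centriole dynamics on the apical cell surface and
    renders them as calibrated two-channel 3D time-lapse stacks; corrects
    whole-cell drift by phase-correlation registration; detects and links
    centriole spots into tracks and assigns mother/daughter roles by
    apicality; measures inter-centriole distances, drift-corrected
    migration speeds, mean squared displacement, and radial/signed-axis
    coordinates; segments trajectories into a confined phase and a
    directed peripheral-migration phase; detects reporter onset,
    trajectory reversal, and drug-induced loss of peripheral position; and
    summarises cohorts with chi-square, t and one-way ANOVA tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
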