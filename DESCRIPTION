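Package: spectransfer
Title: Transferable Hyperspectral Screening of Glyphosate-Resistant Maize
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying glyphosate-resistant maize cultivars from
    visible/near-infrared leaf reflectance across independent experiments.
    Implements the full pipeline: black/white calibration and leaf extraction
    from hyperspectral cubes, a sixteen-index spectral feature registry,
    ANOVA with Holm-Bonferroni pairwise screening and compact letter
    displays, deterministic Kennard-Stone partitioning, primal Transfer
    Component Analysis (TCA), source-domain updating, and linear support
    vector machine classification over cross-experiment transfer tasks,
    with confusion-matrix metrics that treat the resistant-treated group as
    the positive class. A seeded synthetic-data generator emulates the
    class, time-course, and between-experiment domain-shift structure of
    the original study so every stage is testable without the raw imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
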