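Package: bioinkr
Title: Morphometry of Stem-Cell Aggregates and Rheology of Wholly Cellular Bioinks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying suspension cultures of human induced
    pluripotent stem cell aggregates and the jammed, wholly cellular bioinks
    made from them. Provides a multi-pass rough circular Hough transform for
    detecting near-circular aggregates in 8-bit brightfield images, two
    circularity scores (isoperimetric and harmonic-mean area ratio),
    distribution summaries and rank-sum comparisons, culture growth
    bookkeeping, and constitutive rheological modelling: a thixotropic
    Herschel-Bulkley flow model and a fractional Jeffrey viscoelastic model,
    each with forward evaluation and bounded multi-start least-squares
    fitting. A seeded synthetic-data module generates ground-truthed
    brightfield fields and rheograms so every stage can be benchmarked
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    png,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
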