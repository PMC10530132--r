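Package: pelletr
Title: Medium Screening, Taguchi Optimization and Image Morphometry for
    Fungal Pellet Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing submerged-culture production of edible
    fungal mycelial pellets. Implements two-level Plackett-Burman screening
    with dummy-factor ANOVA and effect-share ranking, Taguchi L9 orthogonal
    array analysis with larger-the-better signal-to-noise ratios, factor
    contributions and additive-model prediction, and image-based pellet
    morphometry (8-connected segmentation, area, perimeter, maximal-caliper
    Feret diameter, circularity, Christiansen uniformity coefficient and
    box-plot summaries). A synthetic-data module generates design-of-
    experiments responses with planted effect structure and pellet images
    with known ground truth so every stage can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
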