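Package: footprint3d
Title: Three-Dimensional Ecological Footprint Accounting and
    Sustainability Typology for City Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ecological footprint and biocapacity accounting for
    city-year panels on a provincial-hectare basis, the revised
    three-dimensional ecological footprint indicators (footprint size,
    footprint depth and their product), a four-type ecological
    sustainability classification based on Ward clustering of the
    standardized size/depth plane, and out-of-bag permutation importance
    of socioeconomic and environmental indicators from random-forest
    regressions.  Includes a synthetic city-panel generator that
    back-solves consumption and land-area inputs from target footprint
    indicators, so the full pipeline can be exercised and validated
    without access to statistical-yearbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
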