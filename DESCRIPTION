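Package: speckleRa
Title: Surface Roughness Measurement from Laser Biospeckle Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative nanoscale surface-roughness (Ra) measurement from
    laser speckle images of biological tissue. Builds multi-distance,
    multi-direction gray-level co-occurrence matrices, extracts eight
    Haralick texture statistics and the asymptotes of their exponential
    distance curves, screens the resulting feature table by pairwise
    correlation, reduces it with principal component analysis, and
    calibrates an exponential mapping between the first principal-component
    score and Ra. A phase-screen speckle simulator generates fully
    self-contained, labelled test data.
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
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
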