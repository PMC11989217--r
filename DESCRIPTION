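Package: teawither
Title: Withering Degree of Fresh Tea Leaves from Image-Classification Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the continuous moisture content (wet basis) of withering
    fresh tea leaves from RGB images. A small convolutional classifier built
    from receptive-field attention convolutions (RFAConv) and cross-stage
    fusion blocks gated by coordinate attention (C2f_CA) assigns softmax
    confidence over withering time-point classes; the expected value of the
    class moisture labels under that distribution yields a continuous moisture
    estimate, which is compared against the 58-66% moderate-withering band.
    Includes a synthetic leaf-image generator for end-to-end testing, the
    classical colour/texture feature extractor used by chemometric baselines,
    and the Rp/RMSEP/RPD evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    EBImage,
    jsonlite,
    utils,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
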