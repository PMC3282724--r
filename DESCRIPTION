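Package: glcmveg
Title: Texture-Based Modeling of Successional Vegetation Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models structural and diversity attributes of secondary
    (successional) tropical forest stands from the texture of very
    high-resolution satellite imagery. Computes first-order (data range,
    skewness) and gray-level co-occurrence matrix (GLCM) texture statistics
    over moving windows of red, near-infrared, NDVI and EVI layers; derives
    per-hectare stand attributes (basal area, canopy cover, density,
    richness, Shannon and Simpson diversity, height) from nested stem
    inventories; exhaustively fits one- to three-predictor linear models of
    log-transformed attributes, ranks them by R-squared and compares model
    sizes by AICc; builds permutation null distributions of the maximal
    R-squared; and assesses predictive power by leave-two-out
    cross-validation. A synthetic successional-scene generator provides
    imagery and stem communities with the statistical structure the analysis
    assumes, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
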