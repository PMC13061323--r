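Package: firescar
Title: Monthly Burned-Area Mapping from Multispectral Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An operational-style monthly burned-area processing chain for
    Sentinel-2-like surface-reflectance time series. Builds cloud-free pre-
    and post-fire median composites and their Normalized Burn Ratio (NBR),
    classifies pixels as burned or unburned with a random forest over 22
    spectral features, and applies four post-classification filters:
    minimum-mapping-unit patch removal, morphological refinement with an NBR
    floor, active-fire hotspot masking of false positives, and repeated-burn
    masking across consecutive months. Includes a synthetic scene generator
    with ground truth for end-to-end testing, stratified map-accuracy
    assessment with confidence intervals, temporal confusion analysis, and
    burn-size distribution statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    randomForest,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
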