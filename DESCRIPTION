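Package: phenomaize
Title: Phenology-Based Maize Mapping from NDVI Time Series with
    Time-Weighted Dynamic Time Warping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies maize pixels in gridded NDVI (Normalized Difference
    Vegetation Index) time series by Time-Weighted Dynamic Time Warping
    (TWDTW) against standard seasonal curves built from labeled field
    samples, followed by area-constrained selection against regional
    planting statistics. Includes a synthetic-landscape generator
    (double-logistic crop phenologies, patch mosaics, noise, cloud gaps),
    accuracy assessment (confusion matrices, user's/producer's/overall
    accuracy, county-level agreement statistics), patch-fragmentation
    metrics, and multi-year planting-frequency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
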