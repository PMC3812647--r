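Package: firescar
Title: Burn-Scar Mapping from Multi-Date Multispectral Imagery and Fire-Regime Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fixed-thresholding burn-scar mapping chain for pre/post-fire
    multispectral image pairs: relative radiometric normalisation,
    cloud/water/shadow masking, change-vector analysis, spectral burn indices
    (NBR, NDVI, multi-date NDVI, albedo), index-threshold classification fused
    with a change mask, median filtering, minimum-mapping-unit enforcement and
    polygonization into attributed burn-scar polygons. Includes the
    polygon-overlay accuracy protocol (detected/false/skipped burnt area,
    commission and omission errors), fire-regime analytics (fire-size
    distribution, altitudinal distribution over a DEM, chi-square land-cover
    fire-proneness), and a seedable synthetic-scene generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
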