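Package: popfine
Title: Partition-Based Dasymetric Refinement of Gridded Population Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines coarse gridded population surfaces (WorldPop-style
    equal-area rasters) to a nested finer grid using land-use polygons as
    ancillary data. Coarse cells are stratified into density levels with the
    Fisher-Jenks natural-breaks classifier; within each stratum a land-class
    weight is estimated and combined with within-cell area weights into a
    dual-constraint composite weight that reallocates each cell's population
    across its land classes; class populations are then downscaled
    dasymetrically to nested sub-cells, with an all-water zeroing rule that
    redistributes mass within the parent cell. Includes mass-conserving
    apportionment to administrative units, an evaluation suite (standard
    deviation, percent root-mean-square error, coefficient of determination)
    against census tables, and a synthetic scenario generator producing
    co-registered fixtures with known ground truth. Raster I/O uses the ESRI
    ASCII grid format; vector I/O uses GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
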