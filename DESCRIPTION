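Package: regrowmap
Title: Annual Secondary-Forest Increment, Extent, Loss and Age Mapping from
    Land-Cover Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a time series of annual categorical land-cover rasters
    (e.g. MapBiomas collections) into annual maps of secondary-forest
    increment, extent, loss and age using per-pixel transition rules: a pixel
    enters the secondary-forest pool when an anthropic cover (pasture,
    agriculture, plantation, urban, mining) is replaced by forest, ages one
    year per consecutive forest year, and is reset to zero when cleared.
    Includes linear net carbon-uptake accounting with an age cap and zonal
    (biome) aggregation, map-agreement validation via grid-cell proportions,
    bootstrap regression statistics and Mann-Whitney tests stratified by
    proportion interval, a synthetic landscape simulator with exact
    ground-truth ages for testing, and a minimal single-band GeoTIFF
    reader/writer so stacks can be processed without external geospatial
    system libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
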