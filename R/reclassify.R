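# Step 1 of the pipeline: collapse categorical land-cover maps into binary
# masks. Forest means the forest-formation class only -- mangrove and
# plantation stay out, so old-growth and pre-record secondary forest are one
# undifferentiated "forest" class here.

.reclass_mask <- function(cr, codes) {
  v <- cr$values
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok] <- as.integer(v[ok] %in% codes)
  binary_mask(out, cr$year, cr$grid)
}

#' Binary forest mask (Step 1)
#'
#' 1 where the class code is in the legend's forest set, 0 elsewhere --
#' including the excluded forest-like covers (mangrove, plantation) and all
#' anthropic and natural non-forest covers. Nodata is preserved.
#'
#' @param cr a [class_raster()].
#' @param legend a [legend_config()].
#' @return a [binary_mask()] for the same year and grid.
#' @export
forest_mask <- function(cr, legend = legend_config()) {
  .reclass_mask(cr, legend$forest)
}

#' Binary anthropic-cover mask
#'
#' 1 where the class code is one of the anthropic covers that can precede a
#' regrowth event (plantation, pasture, agriculture, mosaic, urban, mining),
#' 0 elsewhere. Nodata is preserved. Natural non-forest covers (savanna,
#' grassland, water, ...) map to 0: regrowth after them is never counted as
#' secondary forest.
#'
#' @inheritParams forest_mask
#' @return a [binary_mask()].
#' @export
anthropic_mask <- function(cr, legend = legend_config()) {
  .reclass_mask(cr, legend$anthropic)
}
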