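# Domain containers shared by the whole pipeline.
#
# All rasters live in memory as integer matrices (row 1 = northernmost row,
# following the GeoTIFF upper-left convention) with NA marking nodata cells;
# the nodata code in the GridSpec is used only at the file boundary. Every
# multi-raster operation first checks grid alignment -- no resampling or
# reprojection is ever performed.

#' Grid specification
#'
#' Describes the shared grid all rasters in an analysis must live on:
#' dimensions, affine geotransform, CRS identifier and file-level nodata code.
#' Two grids are *aligned* iff every field is equal; all multi-raster
#' operations require alignment (see [assert_aligned()]).
#'
#' @param n_rows,n_cols positive integer dimensions.
#' @param transform length-6 geotransform `c(x0, dx, rx, y0, ry, dy)`
#'   (upper-left corner convention, as in [write_geotiff()]).
#' @param crs_id free-text CRS identifier, e.g. `"EPSG:4326"`.
#' @param nodata_value integer code used for nodata on disk.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, transform = c(0, 1, 0, 0, 0, -1),
                      crs_id = "EPSG:4326", nodata_value = 0L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L) stopf("grid dimensions must be positive")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, transform = as.double(transform),
         crs_id = as.character(crs_id), nodata_value = as.integer(nodata_value)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d, %s, nodata=%d\n",
              x$n_rows, x$n_cols, x$crs_id, x$nodata_value))
  invisible(x)
}

.new_raster <- function(values, year, grid, class, extra_class = NULL) {
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stopf("values are %dx%d but grid is %dx%d",
          nrow(values), ncol(values), grid$n_rows, grid$n_cols)
  }
  structure(list(values = values, year = as.integer(year), grid = grid),
            class = c(extra_class, class, "grid_raster"))
}

#' Categorical land-cover raster for one year
#'
#' @param values integer matrix of legend class codes (`NA` = nodata).
#' @param year calendar year the map describes.
#' @param grid a [grid_spec()].
#' @return an object of class `class_raster`.
#' @export
class_raster <- function(values, year, grid) {
  .new_raster(values, year, grid, "class_raster")
}

#' Binary (0/1) mask raster
#'
#' Used for forest/anthropic reclassifications, the maximum-water-extent mask,
#' and the increment/extent/loss products. Only 0, 1 and `NA` are allowed.
#'
#' @inheritParams class_raster
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(values, year, grid) {
  r <- .new_raster(values, year, grid, "binary_mask")
  bad <- r$values[!is.na(r$values)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stopf("binary mask contains values other than 0/1/NA")
  }
  r
}

#' Secondary-forest age raster
#'
#' Non-negative integer ages in years; 0 means "not secondary forest". In a
#' record starting at `start_year`, ages in year `y` are bounded by
#' `y - start_year` (the oldest detectable regrowth began at the first
#' observable transition).
#'
#' @inheritParams class_raster
#' @return an object of class `age_raster`.
#' @export
age_raster <- function(values, year, grid) {
  r <- .new_raster(values, year, grid, "age_raster")
  if (any(r$values < 0L, na.rm = TRUE)) stopf("ages must be non-negative")
  r
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> year %d, %d x %d, %d nodata px, value range [%s, %s]\n",
              class(x)[1], x$year, x$grid$n_rows, x$grid$n_cols,
              sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Ordered stack of annual class rasters
#'
#' The algorithm's sole primary input: one categorical map per calendar year,
#' consecutive with no gaps, all on one aligned grid, spanning at least two
#' years (so at least one transition is observable).
#'
#' @param rasters list of [class_raster()] objects (any order; sorted by year).
#' @return an object of class `annual_stack` with elements `rasters` (named by
#'   year), `start_year`, `end_year`, and `grid`.
#' @export
annual_stack <- function(rasters) {
  if (length(rasters) < 2L) stopf("a stack needs at least two annual maps")
  years <- vapply(rasters, function(r) r$year, integer(1))
  rasters <- rasters[order(years)]
  years <- sort(years)
  if (anyDuplicated(years)) stopf("duplicate years in stack: %s",
                                  paste(years[duplicated(years)], collapse = ", "))
  if (!all(diff(years) == 1L)) {
    stopf("years must be consecutive; gap after %s",
          years[which(diff(years) != 1L)[1]])
  }
  assert_aligned(rasters)
  names(rasters) <- years
  structure(list(rasters = rasters, start_year = years[1],
                 end_year = years[length(years)], grid = rasters[[1]]$grid),
            class = "annual_stack")
}

#' @export
print.annual_stack <- function(x, ...) {
  cat(sprintf("<annual_stack> %d-%d (%d maps), %d x %d\n", x$start_year,
              x$end_year, length(x$rasters), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Check that rasters share one grid
#'
#' Returns silently iff every object's `grid_spec` equals the first one's;
#' otherwise errors naming the first mismatching field. Alignment is exact
#' (transforms compared to 1e-9 relative tolerance to allow for double
#' round-trips through files).
#'
#' @param rasters non-empty list of grid-bearing objects (`grid_raster`s,
#'   stacks, or bare `grid_spec`s).
#' @return `TRUE`, invisibly.
#' @export
assert_aligned <- function(rasters) {
  if (length(rasters) == 0L) stopf("no rasters to align")
  grids <- lapply(rasters, function(r) if (inherits(r, "grid_spec")) r else r$grid)
  ref <- grids[[1]]
  for (g in grids[-1]) {
    for (field in c("n_rows", "n_cols", "transform", "crs_id", "nodata_value")) {
      a <- ref[[field]]; b <- g[[field]]
      same <- if (field == "transform") {
        isTRUE(all.equal(a, b, tolerance = 1e-9))
      } else {
        identical(a, b)
      }
      if (!same) stopf("grids are not aligned: field '%s' differs (%s vs %s)",
                       field, paste(a, collapse = " "), paste(b, collapse = " "))
    }
  }
  invisible(TRUE)
}

#' Read a categorical land-cover GeoTIFF
#'
#' Reads a single-band integer GeoTIFF as a [class_raster()]. Codes absent
#' from the legend are legal (they are treated as natural non-forest cover by
#' the reclassification step) but trigger a once-per-code warning.
#'
#' @param path path to a single-band integer GeoTIFF.
#' @param year calendar year of the map.
#' @param legend a [legend_config()]; used to vet codes and supply the nodata
#'   value when the file declares none.
#' @return a [class_raster()].
#' @export
read_class_raster <- function(path, year, legend = legend_config()) {
  g <- read_geotiff(path)
  nodata <- if (is.na(g$nodata_value)) legend$nodata_value else g$nodata_value
  values <- g$values
  if (is.na(g$nodata_value)) values[values == nodata] <- NA_integer_
  unknown <- setdiff(unique(values[!is.na(values)]), legend_known_codes(legend))
  for (code in sort(unknown)) {
    warnf("unknown legend code %d in %s; treating as natural non-forest",
          code, path)
  }
  grid <- grid_spec(nrow(values), ncol(values), g$transform, g$crs_id, nodata)
  class_raster(values, year, grid)
}

#' Write a product raster to GeoTIFF
#'
#' Writes a [binary_mask()] or [age_raster()] as a deflate-compressed
#' single-band GeoTIFF. Binary masks are stored as 8-bit, ages as 16-bit
#' (room for any realistic record length). `NA` cells are written as the
#' nodata code; because 0 is a meaningful product value ("not secondary
#' forest" / age zero), the grid's nodata code is used only when it does not
#' alias any data value, otherwise the package's product convention applies
#' (255 for masks, 65535 for ages). Values round-trip bit-exactly through
#' [read_geotiff()] / [read_product_raster()].
#'
#' @param raster a [binary_mask()] or [age_raster()].
#' @param path output path (parent directory must exist).
#' @param nodata_value optional explicit file nodata code; must not collide
#'   with data values.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, nodata_value = NULL) {
  if (!inherits(raster, "grid_raster")) stopf("`raster` must be a raster object")
  g <- raster$grid
  is_age <- inherits(raster, "age_raster")
  bits <- if (is_age) 16L else 8L
  nodata <- nodata_value %||% g$nodata_value
  if (is.null(nodata_value) && any(raster$values == nodata, na.rm = TRUE)) {
    nodata <- if (is_age) 65535L else 255L
  }
  if (any(raster$values == nodata, na.rm = TRUE)) {
    stopf("nodata code %d collides with data values", nodata)
  }
  write_geotiff(raster$values, path, transform = g$transform, crs_id = g$crs_id,
                nodata_value = nodata, bits = bits)
}

#' Read back a product raster
#'
#' Inverse of [write_raster()]: reads a GeoTIFF written by this package as a
#' [binary_mask()] or [age_raster()].
#'
#' @param path GeoTIFF path.
#' @param year calendar year to stamp on the raster.
#' @param kind `"binary"` or `"age"`.
#' @return a [binary_mask()] or [age_raster()].
#' @export
read_product_raster <- function(path, year, kind = c("binary", "age")) {
  kind <- match.arg(kind)
  g <- read_geotiff(path)
  nodata <- if (is.na(g$nodata_value)) 255L else g$nodata_value
  grid <- grid_spec(nrow(g$values), ncol(g$values), g$transform, g$crs_id, nodata)
  if (kind == "binary") binary_mask(g$values, year, grid)
  else age_raster(g$values, year, grid)
}
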