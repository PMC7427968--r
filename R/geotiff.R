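# Minimal single-band GeoTIFF codec.
#
# Supports exactly what the mapping pipeline needs: classic (non-BigTIFF)
# single-band integer rasters, strip-organised, uncompressed or deflate
# (Adobe, code 8), with the GeoTIFF georeferencing tags (pixel scale +
# tiepoint, geo-key directory) and the GDAL nodata convention (tag 42113).
# Deflate streams are zlib-wrapped, which is what memCompress(type = "gzip")
# emits. Tiled layouts, floating-point samples, predictors and multi-band
# files are rejected with a clear error.

.TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.ru32 <- function(con) {
  x <- readBin(con, "integer", n = 1L, size = 4L, endian = attr(con, "endian"))
  if (x < 0) x + 2^32 else as.double(x)
}

# ---- low-level write helpers (always little-endian) -------------------------

.w16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.w32 <- function(x) {
  x <- as.double(x)
  if (any(x > 2^31 - 1)) stopf("raster too large for classic TIFF offsets")
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}
.wdbl <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

.pack_pixels <- function(v, bits) {
  switch(as.character(bits),
    "8"  = as.raw(v),
    "16" = writeBin(v, raw(), size = 2L, endian = "little"),
    "32" = writeBin(v, raw(), size = 4L, endian = "little"),
    stopf("unsupported bit depth: %s", bits)
  )
}

# one 12-byte IFD entry; `value` is pre-encoded raw if longer than 4 bytes
.ifd_entry <- function(tag, type, count, raw_value, overflow_offset = NULL) {
  field <- if (is.null(overflow_offset)) {
    c(raw_value, raw(4L - length(raw_value)))
  } else {
    .w32(overflow_offset)
  }
  c(.w16(tag), .w16(type), .w32(count), field)
}

#' Write a single-band integer GeoTIFF
#'
#' Writes an integer matrix as a deflate-compressed, strip-organised,
#' single-band GeoTIFF with pixel-scale/tiepoint georeferencing and the GDAL
#' nodata tag. `NA` cells are stored as `nodata_value`. Round-trips bit-exactly
#' through [read_geotiff()].
#'
#' @param values integer matrix (row 1 = top of the image); `NA` allowed.
#' @param path output file path; the parent directory must exist.
#' @param transform length-6 geotransform `c(x0, dx, rx, y0, ry, dy)` mapping
#'   pixel (col, row) to world via `x = x0 + col*dx + row*rx`,
#'   `y = y0 + col*ry + row*dy` (upper-left corner convention). Rotation terms
#'   `rx`, `ry` must be zero.
#' @param crs_id free-text CRS identifier; strings of the form `"EPSG:<code>"`
#'   are additionally encoded as the matching geo-key.
#' @param nodata_value integer code written for `NA` cells and recorded in the
#'   nodata tag.
#' @param bits bit depth (8, 16 or 32); chosen automatically from the value
#'   range when `NULL`.
#' @param compress use deflate compression (default `TRUE`).
#' @return `path`, invisibly.
#' @seealso [read_geotiff()]
#' @export
write_geotiff <- function(values, path, transform = c(0, 1, 0, 0, 0, -1),
                          crs_id = "EPSG:4326", nodata_value = 0L,
                          bits = NULL, compress = TRUE) {
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  if (!dir.exists(dirname(path))) stopf("directory does not exist: %s", dirname(path))
  transform <- as.double(transform)
  if (length(transform) != 6L) stopf("`transform` must have 6 elements")
  if (transform[3] != 0 || transform[5] != 0) {
    stopf("rotated grids are not supported (rx, ry must be 0)")
  }
  v <- as.integer(t(values))
  v[is.na(v)] <- as.integer(nodata_value)
  if (any(v < 0L)) stopf("negative pixel values are not supported")
  vmax <- max(v, 0L)
  if (is.null(bits)) bits <- if (vmax <= 255L) 8L else if (vmax <= 65535L) 16L else 32L
  if (vmax >= 2^bits) stopf("value %d does not fit in %d bits", vmax, bits)

  n_rows <- nrow(values); n_cols <- ncol(values)
  pix <- .pack_pixels(v, bits)
  strip <- if (compress) memCompress(pix, type = "gzip") else pix

  # geo keys: model type + citation (+ EPSG code when parseable)
  epsg <- if (grepl("^EPSG:[0-9]+$", crs_id)) as.integer(sub("^EPSG:", "", crs_id)) else NA_integer_
  citation <- paste0(crs_id, "|")
  ascii_raw <- c(charToRaw(citation), as.raw(0L))
  geographic <- !is.na(epsg) && epsg >= 4000L && epsg < 5000L
  keys <- list(c(1024L, 0L, 1L, if (is.na(epsg)) 0L else if (geographic) 2L else 1L),
               c(1026L, 34737L, nchar(citation) + 1L, 0L))
  if (!is.na(epsg)) {
    keys <- c(keys, list(c(if (geographic) 2048L else 3072L, 0L, 1L, epsg)))
    keys <- keys[order(vapply(keys, `[`, integer(1), 1L))]
  }
  gkd <- c(1L, 1L, 0L, length(keys), unlist(keys))

  scale <- c(transform[2], -transform[6], 0)
  tiepoint <- c(0, 0, 0, transform[1], transform[4], 0)
  nodata_raw <- c(charToRaw(as.character(as.integer(nodata_value))), as.raw(0L))

  strip_offset <- 8L
  strip_bytes <- length(strip)              # true byte count, before padding
  if (strip_bytes %% 2L == 1L) strip <- c(strip, as.raw(0L))
  ifd_offset <- 8L + length(strip)

  entries <- list(
    list(256L, 4L, 1L, .w32(n_cols)),
    list(257L, 4L, 1L, .w32(n_rows)),
    list(258L, 3L, 1L, .w16(bits)),
    list(259L, 3L, 1L, .w16(if (compress) 8L else 1L)),
    list(262L, 3L, 1L, .w16(1L)),
    list(273L, 4L, 1L, .w32(strip_offset)),
    list(277L, 3L, 1L, .w16(1L)),
    list(278L, 4L, 1L, .w32(n_rows)),
    list(279L, 4L, 1L, .w32(strip_bytes)),
    list(339L, 3L, 1L, .w16(1L)),
    list(33550L, 12L, 3L, .wdbl(scale)),
    list(33922L, 12L, 6L, .wdbl(tiepoint)),
    list(34735L, 3L, length(gkd), .w16(gkd)),
    list(34737L, 2L, length(ascii_raw), ascii_raw),
    list(42113L, 2L, length(nodata_raw), nodata_raw)
  )

  n_ent <- length(entries)
  overflow_offset <- ifd_offset + 2L + 12L * n_ent + 4L
  ifd <- .w16(n_ent)
  overflow <- raw(0)
  for (e in entries) {
    rv <- e[[4]]
    if (length(rv) <= 4L) {
      ifd <- c(ifd, .ifd_entry(e[[1]], e[[2]], e[[3]], rv))
    } else {
      if (length(rv) %% 2L == 1L) rv <- c(rv, as.raw(0L))
      ifd <- c(ifd, .ifd_entry(e[[1]], e[[2]], e[[3]], rv,
                               overflow_offset + length(overflow)))
      overflow <- c(overflow, rv)
    }
  }
  ifd <- c(ifd, .w32(0L))

  header <- c(charToRaw("II"), .w16(42L), .w32(ifd_offset))
  writeBin(c(header, strip, ifd, overflow), path)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

.read_entry_values <- function(buf, entry, endian) {
  type <- entry$type; count <- entry$count
  size <- .TIFF_TYPE_SIZE[type]
  nbytes <- size * count
  bytes <- if (nbytes <= 4L) entry$field[seq_len(nbytes)] else {
    off <- entry$offset
    buf[(off + 1L):(off + nbytes)]
  }
  switch(as.character(type),
    "2" = rawToChar(bytes[bytes != as.raw(0L)]),
    "1" = as.integer(bytes),
    "3" = readBin(bytes, "integer", n = count, size = 2L, signed = FALSE, endian = endian),
    "4" = {
      x <- readBin(bytes, "integer", n = count, size = 4L, endian = endian)
      ifelse(x < 0, x + 2^32, as.double(x))
    },
    "8" = readBin(bytes, "integer", n = count, size = 2L, signed = TRUE, endian = endian),
    "9" = readBin(bytes, "integer", n = count, size = 4L, endian = endian),
    "12" = readBin(bytes, "double", n = count, size = 8L, endian = endian),
    stopf("unsupported TIFF field type %d", type)
  )
}

.parse_ifd <- function(buf, offset, endian) {
  u16 <- function(at) readBin(buf[(at + 1L):(at + 2L)], "integer", size = 2L,
                              signed = FALSE, endian = endian)
  u32 <- function(at) {
    x <- readBin(buf[(at + 1L):(at + 4L)], "integer", size = 4L, endian = endian)
    if (x < 0) x + 2^32 else as.double(x)
  }
  n <- u16(offset)
  entries <- list()
  for (i in seq_len(n)) {
    at <- offset + 2L + (i - 1L) * 12L
    tag <- u16(at); type <- u16(at + 2L); count <- u32(at + 4L)
    field <- buf[(at + 9L):(at + 12L)]
    entries[[as.character(tag)]] <- list(
      tag = tag, type = type, count = count, field = field, offset = u32(at + 8L)
    )
  }
  entries
}

#' Read a single-band integer GeoTIFF
#'
#' Reads strip-organised single-band integer TIFFs (uncompressed or deflate)
#' together with their georeferencing and nodata metadata. Cells equal to the
#' file's nodata code are returned as `NA`.
#'
#' @param path path to a readable GeoTIFF file.
#' @return a list with `values` (integer matrix, `NA` = nodata), `transform`
#'   (length-6 geotransform), `crs_id`, and `nodata_value` (`NA` if the file
#'   declares none).
#' @seealso [write_geotiff()]
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  buf <- readBin(path, "raw", n = file.size(path))
  order_mark <- rawToChar(buf[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stopf("not a TIFF file: %s", path))
  magic <- readBin(buf[3:4], "integer", size = 2L, signed = FALSE, endian = endian)
  if (magic == 43L) stopf("BigTIFF is not supported: %s", path)
  if (magic != 42L) stopf("not a TIFF file: %s", path)
  ifd_offset <- readBin(buf[5:8], "integer", size = 4L, endian = endian)
  if (ifd_offset < 0) ifd_offset <- ifd_offset + 2^32
  ifd <- .parse_ifd(buf, ifd_offset, endian)

  val <- function(tag, default = NULL) {
    e <- ifd[[as.character(tag)]]
    if (is.null(e)) default else .read_entry_values(buf, e, endian)
  }

  if (!is.null(ifd[["322"]])) stopf("tiled TIFFs are not supported: %s", path)
  spp <- val(277L, 1L)
  if (spp != 1L) stopf("expected a single-band raster, found %d bands: %s", spp, path)
  bits <- val(258L, 1L)
  if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L)) {
    stopf("unsupported bit depth (%s): %s", paste(bits, collapse = ","), path)
  }
  fmt <- val(339L, 1L)
  if (!fmt %in% c(1L, 2L)) stopf("non-integer pixel type (SampleFormat %d): %s", fmt, path)
  compression <- val(259L, 1L)
  if (!compression %in% c(1L, 8L, 32946L)) {
    stopf("unsupported compression %d (only none/deflate): %s", compression, path)
  }
  if (val(317L, 1L) != 1L) stopf("TIFF predictors are not supported: %s", path)

  n_cols <- as.integer(val(256L)); n_rows <- as.integer(val(257L))
  offsets <- val(273L); counts <- val(279L)
  pix_raw <- do.call(c, lapply(seq_along(offsets), function(i) {
    chunk <- buf[(offsets[i] + 1L):(offsets[i] + counts[i])]
    if (compression == 1L) chunk else memDecompress(chunk, type = "gzip")
  }))

  n_px <- n_rows * n_cols
  v <- switch(as.character(bits),
    "8"  = as.integer(pix_raw[seq_len(n_px)]),
    "16" = readBin(pix_raw, "integer", n = n_px, size = 2L,
                   signed = (fmt == 2L), endian = endian),
    "32" = readBin(pix_raw, "integer", n = n_px, size = 4L, endian = endian)
  )
  values <- matrix(v, nrow = n_rows, ncol = n_cols, byrow = TRUE)

  scale <- val(33550L); tie <- val(33922L); mt <- val(34264L)
  transform <- if (!is.null(scale) && !is.null(tie)) {
    c(tie[4] - tie[1] * scale[1], scale[1], 0, tie[5] + tie[2] * scale[2], 0, -scale[2])
  } else if (!is.null(mt)) {
    c(mt[4], mt[1], mt[2], mt[8], mt[5], mt[6])
  } else {
    c(0, 1, 0, 0, 0, -1)
  }

  crs_id <- ""
  gkd <- val(34735L)
  if (!is.null(gkd) && length(gkd) >= 4L) {
    nk <- gkd[4]
    keys <- if (nk > 0) matrix(gkd[5:(4 + 4 * nk)], ncol = 4L, byrow = TRUE) else
      matrix(integer(0), ncol = 4L)
    code_row <- which(keys[, 1] %in% c(2048L, 3072L) & keys[, 2] == 0L)
    cit_row <- which(keys[, 1] == 1026L & keys[, 2] == 34737L)
    if (length(code_row)) {
      crs_id <- paste0("EPSG:", keys[code_row[1], 4])
    } else if (length(cit_row)) {
      ascii <- val(34737L, "")
      part <- substr(ascii, keys[cit_row[1], 4] + 1L,
                     keys[cit_row[1], 4] + keys[cit_row[1], 3])
      crs_id <- sub("\\|.*$", "", part)
    }
  }

  nodata_value <- NA_integer_
  nd <- val(42113L)
  if (!is.null(nd)) {
    nodata_value <- suppressWarnings(as.integer(as.numeric(trimws(nd))))
    values[values == nodata_value] <- NA_integer_
  }

  list(values = values, transform = transform, crs_id = crs_id,
       nodata_value = nodata_value)
}
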