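# The per-pixel recurrences at the heart of the pipeline.
#
# A pixel enters the secondary-forest pool (increment) when forest replaces an
# anthropic cover between consecutive years, outside the maximum water extent.
# The extent map carries the pool forward, dropping pixels the moment they
# stop being forest; the loss map records those drops; the age map counts
# consecutive forest years since the most recent qualifying event and resets
# to zero on clearing. Everything is a pure function of the input masks, so
# each step is exposed on its own as well as through the timeline driver.

.check_years <- function(prev, cur, what) {
  if (cur$year != prev$year + 1L) {
    stopf("%s: years must be consecutive (got %d then %d)", what, prev$year, cur$year)
  }
}

.mask_logical <- function(m) !is.na(m$values) & m$values == 1L

#' Annual secondary-forest increment (Step 2)
#'
#' A pixel increments in year *y* iff it is forest in *y*, was anthropic in
#' *y - 1*, and lies outside the maximum water extent. Regrowth on natural
#' non-forest covers is never counted. Nodata in either input propagates.
#'
#' @param forest_y forest [binary_mask()] for year *y*.
#' @param anthropic_prev anthropic [binary_mask()] for year *y - 1*.
#' @param water_max optional static maximum-water-extent [binary_mask()];
#'   pixels with value 1 can never increment.
#' @return increment [binary_mask()] for year *y*.
#' @export
increment <- function(forest_y, anthropic_prev, water_max = NULL) {
  .check_years(anthropic_prev, forest_y, "increment")
  assert_aligned(c(list(forest_y, anthropic_prev),
                   if (!is.null(water_max)) list(water_max)))
  inc <- .mask_logical(forest_y) & .mask_logical(anthropic_prev)
  if (!is.null(water_max)) inc <- inc & !.mask_logical(water_max)
  out <- matrix(as.integer(inc), nrow(inc), ncol(inc))
  out[is.na(forest_y$values) | is.na(anthropic_prev$values)] <- NA_integer_
  if (!is.null(water_max)) out[is.na(water_max$values)] <- NA_integer_
  binary_mask(out, forest_y$year, forest_y$grid)
}

#' Annual secondary-forest extent (Step 3)
#'
#' Carries the pool forward: a pixel is in the year-*y* extent iff it was in
#' the year *y - 1* extent or incremented in *y*, and is still forest in *y*.
#' This OR/AND form is equivalent to accumulating the annual sums, mapping
#' values of 2 or more to 1 and multiplying by the forest map (a tested
#' property).
#'
#' @param extent_prev extent [binary_mask()] for year *y - 1*.
#' @param inc_y increment [binary_mask()] for year *y*.
#' @param forest_y forest [binary_mask()] for year *y*.
#' @return extent [binary_mask()] for year *y*.
#' @export
extent_step <- function(extent_prev, inc_y, forest_y) {
  .check_years(extent_prev, inc_y, "extent_step")
  if (inc_y$year != forest_y$year) stopf("extent_step: increment/forest year mismatch")
  assert_aligned(list(extent_prev, inc_y, forest_y))
  ext <- (.mask_logical(extent_prev) | .mask_logical(inc_y)) & .mask_logical(forest_y)
  out <- matrix(as.integer(ext), nrow(ext), ncol(ext))
  out[is.na(extent_prev$values) | is.na(forest_y$values)] <- NA_integer_
  binary_mask(out, forest_y$year, forest_y$grid)
}

#' Annual secondary-forest loss
#'
#' A pixel is lost in year *y* iff it was in the year *y - 1* extent and is
#' not forest in *y*.
#'
#' @inheritParams extent_step
#' @return loss [binary_mask()] for year *y*.
#' @export
loss_step <- function(extent_prev, forest_y) {
  .check_years(extent_prev, forest_y, "loss_step")
  assert_aligned(list(extent_prev, forest_y))
  lost <- .mask_logical(extent_prev) & !.mask_logical(forest_y)
  out <- matrix(as.integer(lost), nrow(lost), ncol(lost))
  out[is.na(extent_prev$values) | is.na(forest_y$values)] <- NA_integer_
  binary_mask(out, forest_y$year, forest_y$grid)
}

#' Annual secondary-forest age (Step 4)
#'
#' Adds the year-*y* extent to the previous ages where the pixel is still
#' forest and resets to zero elsewhere. Pixels outside the extent never
#' accumulate age; a cleared pixel restarts at 1 only on a new qualifying
#' increment.
#'
#' @param age_prev [age_raster()] for year *y - 1*.
#' @param extent_y extent [binary_mask()] for year *y*.
#' @param forest_y forest [binary_mask()] for year *y*.
#' @return [age_raster()] for year *y*.
#' @export
age_step <- function(age_prev, extent_y, forest_y) {
  .check_years(age_prev, extent_y, "age_step")
  if (extent_y$year != forest_y$year) stopf("age_step: extent/forest year mismatch")
  assert_aligned(list(age_prev, extent_y, forest_y))
  f <- .mask_logical(forest_y)
  a <- age_prev$values + extent_y$values
  a[!f] <- 0L
  a[is.na(age_prev$values) | is.na(forest_y$values)] <- NA_integer_
  age_raster(a, forest_y$year, forest_y$grid)
}

#' Run the full increment/extent/loss/age timeline
#'
#' Drives Steps 1-4 over an annual class stack. With a record spanning
#' `start_year..end_year`, increments and extents exist for
#' `start_year + 1 .. end_year` (the first detectable transition), losses for
#' `start_year + 2 .. end_year`, and the first age map only contains one-year
#' old pixels. A pixel that is nodata in any input year (or in the water
#' mask) is nodata in every product for every year.
#'
#' @param stack an [annual_stack()].
#' @param legend a [legend_config()].
#' @param water_max optional static maximum-water-extent [binary_mask()]
#'   aligned with the stack.
#' @return an object of class `regrowth_products`: lists `increments`,
#'   `extents`, `losses`, `ages`, each named by year, plus `start_year`,
#'   `end_year` and `grid`.
#' @export
run_timeline <- function(stack, legend = legend_config(), water_max = NULL) {
  if (!inherits(stack, "annual_stack")) stopf("`stack` must be an annual_stack")
  if (!is.null(water_max)) assert_aligned(list(stack$grid, water_max))
  years <- stack$start_year:stack$end_year
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols

  forest <- lapply(stack$rasters, function(r) !is.na(r$values) & r$values %in% legend$forest)
  anthro <- lapply(stack$rasters, function(r) !is.na(r$values) & r$values %in% legend$anthropic)
  invalid <- Reduce(`|`, lapply(stack$rasters, function(r) is.na(r$values)))
  water <- if (is.null(water_max)) matrix(FALSE, nr, nc) else .mask_logical(water_max)
  if (!is.null(water_max)) invalid <- invalid | is.na(water_max$values)

  as_bin <- function(l, year) {
    m <- matrix(as.integer(l), nr, nc); m[invalid] <- NA_integer_
    binary_mask(m, year, stack$grid)
  }
  as_age <- function(a, year) {
    a[invalid] <- NA_integer_
    age_raster(a, year, stack$grid)
  }

  increments <- extents <- losses <- ages <- list()
  ext_prev <- matrix(FALSE, nr, nc)
  age_prev <- matrix(0L, nr, nc)
  for (i in seq_along(years)[-1]) {
    y <- years[i]; key <- as.character(y)
    f <- forest[[i]]
    inc <- f & anthro[[i - 1]] & !water
    ext <- (ext_prev | inc) & f
    age <- age_prev + as.integer(ext)
    age[!f] <- 0L
    increments[[key]] <- as_bin(inc, y)
    extents[[key]] <- as_bin(ext, y)
    if (i > 2L) losses[[key]] <- as_bin(ext_prev & !f, y)
    ages[[key]] <- as_age(age, y)
    ext_prev <- ext
    age_prev <- age
  }
  structure(list(increments = increments, extents = extents, losses = losses,
                 ages = ages, start_year = stack$start_year,
                 end_year = stack$end_year, grid = stack$grid),
            class = "regrowth_products")
}

#' @export
print.regrowth_products <- function(x, ...) {
  cat(sprintf("<regrowth_products> %d-%d: %d increment/extent, %d loss, %d age maps\n",
              x$start_year, x$end_year, length(x$extents), length(x$losses),
              length(x$ages)))
  invisible(x)
}

#' Per-pixel reference implementation of the age recurrence
#'
#' Scans one pixel's class-code series directly: a regrowth event starts when
#' an anthropic code is followed by a forest code (outside water); age counts
#' consecutive forest years since the most recent event; any non-forest year
#' resets the age to zero; forest runs with no qualifying start stay at zero.
#' Deliberately independent of the raster recurrences -- it is the oracle the
#' engine is tested against.
#'
#' @param class_series integer vector of class codes, one per year, length
#'   at least 2. `NA` anywhere makes the whole series nodata.
#' @param legend a [legend_config()].
#' @param water_flag 1 if the pixel lies in the maximum water extent.
#' @return integer vector of ages for years 2..length(series) (`NA`
#'   throughout if the series contains nodata).
#' @export
pixel_oracle <- function(class_series, legend = legend_config(), water_flag = 0L) {
  n <- length(class_series)
  if (n < 2L) stopf("class series must cover at least two years")
  if (anyNA(class_series)) return(rep(NA_integer_, n - 1L))
  ages <- integer(n - 1L)
  age <- 0L
  for (t in 2:n) {
    if (water_flag == 1L) {
      age <- 0L
    } else if (!(class_series[t] %in% legend$forest)) {
      age <- 0L
    } else if (age > 0L) {
      age <- age + 1L
    } else if (class_series[t - 1L] %in% legend$anthropic) {
      age <- 1L
    } else {
      age <- 0L
    }
    ages[t - 1L] <- age
  }
  ages
}

#' Annual pixel-count bookkeeping of the extent recurrence
#'
#' For each year with a loss map, tabulates the pixel counts entering the
#' conservation identity `|extent_y| = |extent_{y-1}| - |loss_y| +
#' |increment_y|` over valid pixels, together with the residual (always zero
#' for products of [run_timeline()]).
#'
#' @param products a `regrowth_products` object.
#' @return data frame with columns `year`, `extent`, `extent_prev`, `loss`,
#'   `increment`, `residual`.
#' @export
conservation_table <- function(products) {
  yrs <- as.integer(names(products$losses))
  rows <- lapply(yrs, function(y) {
    k <- as.character(y); kp <- as.character(y - 1L)
    ext <- sum(products$extents[[k]]$values, na.rm = TRUE)
    ext_prev <- sum(products$extents[[kp]]$values, na.rm = TRUE)
    lost <- sum(products$losses[[k]]$values, na.rm = TRUE)
    inc <- sum(products$increments[[k]]$values, na.rm = TRUE)
    data.frame(year = y, extent = ext, extent_prev = ext_prev, loss = lost,
               increment = inc, residual = ext - (ext_prev - lost + inc))
  })
  do.call(rbind, rows)
}
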