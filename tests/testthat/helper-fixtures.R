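# Shared fixture builders and independent oracles. Everything is generated in
# code; no stored rasters.

tiny_grid <- function(nr = 2L, nc = 2L, nodata = 0L) {
  grid_spec(nr, nc, transform = c(0, 30, 0, 0, 0, -30),
            crs_id = "EPSG:32722", nodata_value = nodata)
}

mk_mask <- function(m, year = 2000L, grid = NULL) {
  m <- as.matrix(m)
  binary_mask(m, year, grid %||% tiny_grid(nrow(m), ncol(m)))
}

mk_class <- function(m, year = 2000L, grid = NULL) {
  m <- as.matrix(m)
  class_raster(m, year, grid %||% tiny_grid(nrow(m), ncol(m)))
}

mk_age <- function(m, year = 2000L, grid = NULL) {
  m <- as.matrix(m)
  age_raster(m, year, grid %||% tiny_grid(nrow(m), ncol(m)))
}

# a 1x1-pixel annual stack from a vector of class codes
pixel_stack <- function(codes, start_year = 1985L) {
  g <- tiny_grid(1L, 1L)
  annual_stack(lapply(seq_along(codes), function(i) {
    class_raster(matrix(codes[i], 1, 1), start_year + i - 1L, g)
  }))
}

# engine age series of the single pixel, as an integer vector by year
pixel_ages <- function(products) {
  vapply(products$ages, function(a) a$values[1, 1], integer(1), USE.NAMES = FALSE)
}

# brute-force Mann-Whitney U for sample x: pairs won + half the ties
brute_force_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# The accumulate-sum / threshold / multiply formulation of the extent
# recurrence, kept deliberately literal: a running per-pixel sum of past
# membership plus this year's increment, thresholded to binary, then
# multiplied by the annual forest map which also resets the sum of cleared
# pixels.
literal_extents <- function(increments, forests) {
  stopifnot(length(increments) == length(forests))
  cum <- matrix(0L, nrow(increments[[1]]), ncol(increments[[1]]))
  out <- vector("list", length(increments))
  for (i in seq_along(increments)) {
    cum <- cum + increments[[i]]
    ext <- matrix(as.integer(cum >= 1L), nrow(cum), ncol(cum)) * forests[[i]]
    cum <- cum * forests[[i]]
    out[[i]] <- ext
  }
  out
}

# random simulation parameters for property tests (dynamics drawn from the
# provided RNG stream so each case differs but the suite is reproducible)
random_sim_params <- function(seed, nr = 20L, nc = 20L, n_years = 40L) {
  with_local_seed(seed * 7919L, {
    sim_params(
      n_rows = nr, n_cols = nc,
      start_year = 1980L, end_year = 1980L + n_years - 1L,
      init_forest = stats::runif(1, 0.2, 0.6),
      init_anthropic = stats::runif(1, 0.2, 0.4),
      p_clear = stats::runif(1, 0, 0.3),
      p_regrow = stats::runif(1, 0, 0.4),
      p_nat_regrow = stats::runif(1, 0, 0.3),
      water_frac = stats::runif(1, 0, 0.15),
      nodata_frac = sample(c(0, 0.05), 1),
      seed = seed
    )
  })
}

# engine ages flattened to a pixels x years integer matrix
ages_matrix <- function(products) {
  unname(vapply(products$ages, function(a) as.vector(a$values),
                integer(products$grid$n_rows * products$grid$n_cols)))
}
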