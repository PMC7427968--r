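# Carbon accounting on top of an age map.
#
# Model: every secondary-forest pixel accumulates carbon linearly at the
# neotropical mean net uptake rate for its first `age_cap_years` years of
# succession and then stabilises (null net uptake thereafter), so a pixel of
# age a has accumulated min(a, cap) * rate * pixel_area of carbon. The rate
# uncertainty is a single shared (fully correlated) error: every sd output
# scales as rate_sd / rate_mean times the mean, which is why reported
# sd/mean ratios are constant across zones.

#' Carbon-uptake parameters
#'
#' Defaults encode the neotropical secondary-forest mean net uptake rate of
#' 3.05 +/- 0.19 Mg C per hectare per year applied over the first 20 years of
#' succession, on 30-m (0.09 ha) pixels.
#'
#' @param rate_mean mean net uptake rate, Mg C ha^-1 yr^-1.
#' @param rate_sd standard deviation of the rate, Mg C ha^-1 yr^-1.
#' @param age_cap_years years of active uptake before stabilisation.
#' @param pixel_area_ha pixel area in hectares.
#' @return an object of class `carbon_params`.
#' @export
carbon_params <- function(rate_mean = 3.05, rate_sd = 0.19,
                          age_cap_years = 20L, pixel_area_ha = 0.09) {
  if (rate_mean <= 0 || rate_sd < 0 || age_cap_years < 1L || pixel_area_ha <= 0) {
    stopf("carbon parameters must be positive (rate_sd may be 0)")
  }
  structure(list(rate_mean = rate_mean, rate_sd = rate_sd,
                 age_cap_years = as.integer(age_cap_years),
                 pixel_area_ha = pixel_area_ha),
            class = "carbon_params")
}

#' Annual uptake of one pixel
#'
#' The per-pixel annual net uptake while a pixel is younger than the age cap:
#' `rate * pixel_area`. At the defaults this is 0.2745 +/- 0.0171 Mg C per
#' year, printing as 0.275 +/- 0.017 at three decimals (half-up).
#'
#' @param params a [carbon_params()].
#' @return named numeric `c(mean=, sd=)` in Mg C yr^-1.
#' @export
pixel_annual_uptake <- function(params = carbon_params()) {
  c(mean = params$rate_mean * params$pixel_area_ha,
    sd = params$rate_sd * params$pixel_area_ha)
}

.capped_age_years <- function(ages, params) {
  a <- ages$values[!is.na(ages$values)]
  sum(pmin(a, params$age_cap_years))
}

#' Cumulative uptake of an age map
#'
#' Total carbon accumulated by all secondary-forest pixels on the map: each
#' pixel contributes `min(age, cap) * rate * pixel_area`. Pixels older than
#' the cap have stopped taking up carbon but retain their first `cap` years
#' of accumulation. The sd is the fully correlated rate error: `mean *
#' rate_sd / rate_mean`.
#'
#' @param ages an [age_raster()].
#' @param params a [carbon_params()].
#' @return named numeric `c(mean=, sd=)` in Mg C.
#' @export
cumulative_uptake <- function(ages, params = carbon_params()) {
  yrs <- .capped_age_years(ages, params)
  m <- yrs * params$rate_mean * params$pixel_area_ha
  c(mean = m, sd = yrs * params$rate_sd * params$pixel_area_ha)
}

#' Cumulative uptake by zone
#'
#' [cumulative_uptake()] restricted to each zone of a zone raster (e.g.
#' biomes), with each zone's share of the total. Zonal rows sum exactly to
#' the whole-map total (uptake is additive over any partition of pixels).
#'
#' @param ages an [age_raster()].
#' @param zones a [class_raster()] of integer zone codes, aligned with
#'   `ages`; its `NA` cells are excluded.
#' @param params a [carbon_params()].
#' @param zone_labels optional named character vector mapping zone codes to
#'   labels.
#' @return data frame with columns `zone`, `uptake_mean`, `uptake_sd`
#'   (Mg C) and `share_percent`.
#' @export
zonal_uptake <- function(ages, zones, params = carbon_params(),
                         zone_labels = NULL) {
  assert_aligned(list(ages, zones))
  ok <- !is.na(ages$values) & !is.na(zones$values)
  capped <- pmin(ages$values[ok], params$age_cap_years)
  yrs <- tapply(capped, zones$values[ok], sum)
  yrs <- yrs[order(as.integer(names(yrs)))]
  mean_up <- as.numeric(yrs) * params$rate_mean * params$pixel_area_ha
  sd_up <- as.numeric(yrs) * params$rate_sd * params$pixel_area_ha
  total <- sum(mean_up)
  zone <- names(yrs)
  if (!is.null(zone_labels)) {
    zone <- ifelse(zone %in% names(zone_labels), zone_labels[zone], zone)
  }
  data.frame(zone = zone, uptake_mean = mean_up, uptake_sd = sd_up,
             share_percent = if (total > 0) 100 * mean_up / total else
               rep(0, length(mean_up)),
             row.names = NULL)
}

#' Areal extent by zone
#'
#' Pixel counts of a binary mask per zone, converted to km^2
#' (`count * pixel_area_ha / 100`) with each zone's percentage of the total.
#'
#' @param mask a [binary_mask()] (e.g. a secondary-forest extent map).
#' @param zones a [class_raster()] of zone codes aligned with `mask`.
#' @param pixel_area_ha pixel area in hectares.
#' @param zone_labels optional named character vector of zone labels.
#' @return data frame with columns `zone`, `area_km2`, `share_percent`.
#' @export
zonal_extent <- function(mask, zones, pixel_area_ha = 0.09,
                         zone_labels = NULL) {
  assert_aligned(list(mask, zones))
  ok <- !is.na(mask$values) & !is.na(zones$values)
  counts <- tapply(mask$values[ok], zones$values[ok], sum)
  counts <- counts[order(as.integer(names(counts)))]
  area <- as.numeric(counts) * pixel_area_ha / 100
  total <- sum(area)
  zone <- names(counts)
  if (!is.null(zone_labels)) {
    zone <- ifelse(zone %in% names(zone_labels), zone_labels[zone], zone)
  }
  data.frame(zone = zone, area_km2 = area,
             share_percent = if (total > 0) 100 * area / total else
               rep(0, length(area)),
             row.names = NULL)
}

#' Percentage shares of a column of totals
#'
#' Small helper for reported tables: shares of `x` in percent, optionally
#' rounded half-up at `digits` decimals.
#'
#' @param x numeric vector of non-negative totals.
#' @param digits decimals to keep (`NULL` for full precision).
#' @return numeric vector summing to 100 (up to rounding).
#' @export
percent_shares <- function(x, digits = NULL) {
  s <- 100 * x / sum(x)
  if (!is.null(digits)) s <- round_half_up(s, digits)
  s
}
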