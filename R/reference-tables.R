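# Published national summaries of the Brazilian secondary-forest benchmark
# dataset (MapBiomas Collection 4.1 derived, 1986-2018 record). These small
# tables are reference inputs for the reported-arithmetic helpers below and
# for cross-checking a full-scale reproduction of the national products; the
# desk-scale pipeline itself never needs them.

#' Published biome extents of Brazilian secondary forest in 2018
#'
#' Secondary-forest area standing in 2018, by biome, from the national
#' 30-m benchmark mapping (km^2).
#'
#' @return data frame with columns `biome`, `extent_km2`.
#' @export
biome_extent_table <- function() {
  data.frame(
    biome = c("Amazon", "Atlantic Forest", "Caatinga", "Cerrado", "Pampa",
              "Pantanal"),
    extent_km2 = c(148764, 70218, 6106, 34115, 2469, 1120)
  )
}

#' Published biome net carbon uptake of Brazilian secondary forests
#'
#' Cumulative net carbon uptake 1986-2018 by biome (Tg C), with the fully
#' correlated rate standard deviation.
#'
#' @return data frame with columns `biome`, `uptake_tgc`, `uptake_sd_tgc`.
#' @export
biome_uptake_table <- function() {
  data.frame(
    biome = c("Amazon", "Atlantic Forest", "Caatinga", "Cerrado", "Pampa",
              "Pantanal"),
    uptake_tgc = c(436, 260, 17, 111, 8, 3),
    uptake_sd_tgc = c(26.84, 15.98, 1.03, 6.83, 0.52, 0.21)
  )
}

#' Published national forest cover, 1985 and 2018
#'
#' Brazilian forest cover (excluding mangroves and plantations) at the two
#' ends of the record (km^2), from MapBiomas Collection 4.1.
#'
#' @return named numeric `c(y1985=, y2018=)`.
#' @export
national_forest_cover <- function() {
  c(y1985 = 4646516, y2018 = 4079827)
}

#' Forest-cover change between two dates
#'
#' Absolute reduction and its percentage of the initial cover.
#'
#' @param cover_start,cover_end forest cover at the start and end (km^2).
#' @return named numeric `c(reduction_km2=, reduction_percent=)`.
#' @export
forest_cover_change <- function(cover_start, cover_end) {
  red <- cover_start - cover_end
  c(reduction_km2 = red, reduction_percent = 100 * red / cover_start)
}

#' Mean annual uptake from a cumulative total
#'
#' @param total_uptake cumulative uptake over the record (any unit).
#' @param n_years number of years in the record (default 33, the 1986-2018
#'   span).
#' @return mean annual uptake in the same unit per year.
#' @export
mean_annual_uptake <- function(total_uptake, n_years = 33) {
  total_uptake / n_years
}

#' Percentage of emissions offset by secondary-forest uptake
#'
#' @param uptake cumulative uptake (Tg C).
#' @param emissions cumulative emissions over the same period (Tg C).
#' @return offset in percent.
#' @export
uptake_offset_percent <- function(uptake, emissions) {
  100 * uptake / emissions
}
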