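# Legend configuration: which integer class codes play which role.
#
# The default legend follows MapBiomas Collection 4.1: forest formation is
# code 3; mangrove (5) and forest plantation (9) are excluded from the forest
# class; the anthropic covers that can precede a regrowth event are forest
# plantation, pasture, agriculture (annual, semi-perennial and perennial
# crops and the agriculture parent class), mosaic of agriculture and pasture,
# urban infrastructure, and mining. Any code in none of the sets is natural
# non-forest cover and can never seed a secondary forest.

#' Legend configuration
#'
#' Maps integer land-cover codes to the roles the algorithm cares about.
#' `forest` must be disjoint from both other sets. `excluded_forest` lists
#' forest-like covers deliberately kept out of the forest class (mangrove,
#' plantation); plantation also appears among the anthropic covers, because a
#' plantation-to-forest transition is a genuine regrowth event while standing
#' plantation is never counted as forest.
#'
#' @param forest integer codes counted as forest.
#' @param anthropic integer codes of human land uses that can precede
#'   regrowth.
#' @param excluded_forest forest-like codes excluded from the forest class.
#' @param natural integer codes documented as natural non-forest cover
#'   (savanna, grassland, wetland, water, ...). They play no active role --
#'   any code outside the other three sets behaves as natural non-forest --
#'   but codes absent from all four sets trigger a once-per-code warning on
#'   read.
#' @param nodata_value integer nodata code of the class maps.
#' @return an object of class `legend_config`.
#' @export
legend_config <- function(forest = 3L,
                          anthropic = c(9L, 15L, 18L, 19L, 20L, 21L, 24L, 30L, 36L),
                          excluded_forest = c(5L, 9L),
                          natural = c(4L, 10L, 11L, 12L, 13L, 22L, 23L, 25L,
                                      26L, 27L, 29L, 32L, 33L),
                          nodata_value = 0L) {
  forest <- as.integer(forest)
  anthropic <- as.integer(anthropic)
  excluded_forest <- as.integer(excluded_forest)
  natural <- as.integer(natural)
  if (length(intersect(forest, anthropic)) ||
      length(intersect(forest, excluded_forest))) {
    stopf("forest codes must be disjoint from anthropic and excluded codes")
  }
  structure(list(forest = forest, anthropic = anthropic,
                 excluded_forest = excluded_forest, natural = natural,
                 nodata_value = as.integer(nodata_value)),
            class = "legend_config")
}

legend_known_codes <- function(legend) {
  unique(c(legend$forest, legend$anthropic, legend$excluded_forest,
           legend$natural))
}

#' @export
print.legend_config <- function(x, ...) {
  cat(sprintf("<legend_config> forest={%s} anthropic={%s} excluded={%s} nodata=%d\n",
              paste(x$forest, collapse = ","), paste(x$anthropic, collapse = ","),
              paste(x$excluded_forest, collapse = ","), x$nodata_value))
  invisible(x)
}

#' Read a legend from a YAML file
#'
#' Expects keys `forest`, `anthropic`, `excluded_forest` (integer lists) and
#' `nodata` (scalar); missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return a [legend_config()].
#' @export
read_legend <- function(path) {
  if (!file.exists(path)) stopf("legend file not found: %s", path)
  y <- yaml::read_yaml(path)
  d <- legend_config()
  legend_config(forest = y$forest %||% d$forest,
                anthropic = y$anthropic %||% d$anthropic,
                excluded_forest = y$excluded_forest %||% d$excluded_forest,
                natural = y$natural %||% d$natural,
                nodata_value = y$nodata %||% d$nodata_value)
}
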