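# Synthetic annual land-cover stacks with exact ground-truth ages.
#
# The generator emulates the Markov-like dynamics the mapping algorithm
# consumes: pixels start as forest, pasture (anthropic) or savanna (natural
# non-forest) in stated proportions, then flip each year with per-transition
# probabilities (clearing, regrowth on anthropic land, regrowth on natural
# land). A static maximum-water-extent mask covers a configurable fraction of
# pixels. Ground-truth ages are tracked during generation with the same
# consecutive-run rule the pixel oracle uses, but in a separate code path, so
# generator and engine are independent implementations of one recurrence.
# Natural regrowth is on by default precisely so tests can confirm the engine
# ignores it.

#' Simulation parameters for synthetic landscapes
#'
#' Defaults emulate a Brazilian-style 34-year record (1985-2018) on a small
#' grid with slow clearing, faster regrowth on abandoned anthropic land, and
#' occasional regrowth on natural non-forest cover.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param start_year,end_year first and last mapped year.
#' @param forest_code,anthropic_code,natural_code class codes emitted for the
#'   three simulated covers (defaults follow the MapBiomas legend: forest
#'   formation 3, pasture 15, savanna 4).
#' @param init_forest,init_anthropic initial cover proportions (the rest is
#'   natural non-forest).
#' @param p_clear annual probability forest -> anthropic.
#' @param p_regrow annual probability anthropic -> forest.
#' @param p_nat_regrow annual probability natural non-forest -> forest.
#' @param water_frac fraction of pixels inside the maximum water extent.
#' @param nodata_frac fraction of pixels that are nodata in every year.
#' @param seed integer seed; regeneration with the same parameters is
#'   bit-identical.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_rows = 60L, n_cols = 60L,
                       start_year = 1985L, end_year = 2018L,
                       forest_code = 3L, anthropic_code = 15L,
                       natural_code = 4L,
                       init_forest = 0.5, init_anthropic = 0.35,
                       p_clear = 0.02, p_regrow = 0.05, p_nat_regrow = 0.02,
                       water_frac = 0.05, nodata_frac = 0, seed = 42L) {
  probs <- c(p_clear, p_regrow, p_nat_regrow, water_frac, nodata_frac,
             init_forest, init_anthropic)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (init_forest + init_anthropic > 1) stopf("initial proportions exceed 1")
  if (end_year - start_year < 1L) stopf("need at least two years")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 forest_code = as.integer(forest_code),
                 anthropic_code = as.integer(anthropic_code),
                 natural_code = as.integer(natural_code),
                 init_forest = init_forest, init_anthropic = init_anthropic,
                 p_clear = p_clear, p_regrow = p_regrow,
                 p_nat_regrow = p_nat_regrow, water_frac = water_frac,
                 nodata_frac = nodata_frac, seed = as.integer(seed)),
            class = "sim_params")
}

#' Legend matching the synthetic class codes
#'
#' @param params a [sim_params()].
#' @return a [legend_config()] whose forest/anthropic sets are the simulated
#'   codes.
#' @export
sim_legend <- function(params) {
  legend_config(forest = params$forest_code,
                anthropic = params$anthropic_code,
                excluded_forest = integer(0),
                natural = params$natural_code,
                nodata_value = 0L)
}

#' Generate a synthetic annual class stack with ground-truth ages
#'
#' Simulates per-pixel annual transitions under `params` and returns the
#' class stack, the static maximum-water-extent mask, and the exact
#' secondary-forest age a correct mapping algorithm must reproduce for every
#' pixel and year (ages for `start_year + 1 .. end_year`).
#'
#' @param params a [sim_params()].
#' @return list with `stack` ([annual_stack()]), `water_max`
#'   ([binary_mask()]), `truth_ages` (list of [age_raster()] named by year)
#'   and `legend` (the matching [legend_config()]).
#' @export
generate_stack <- function(params = sim_params()) {
  p <- params
  n <- p$n_rows * p$n_cols
  years <- p$start_year:p$end_year
  grid <- grid_spec(p$n_rows, p$n_cols,
                    transform = c(0, 30, 0, 0, 0, -30), crs_id = "EPSG:32722",
                    nodata_value = 0L)
  with_local_seed(p$seed, {
    u <- stats::runif(n)
    cur <- ifelse(u < p$init_forest, p$forest_code,
                  ifelse(u < p$init_forest + p$init_anthropic,
                         p$anthropic_code, p$natural_code))
    water <- as.integer(stats::runif(n) < p$water_frac)
    nodata <- stats::runif(n) < p$nodata_frac

    rasters <- vector("list", length(years))
    truth <- vector("list", length(years) - 1L)
    age <- integer(n)
    for (i in seq_along(years)) {
      if (i > 1L) {
        prev <- cur
        r <- stats::runif(n)
        cur <- prev
        cur[prev == p$forest_code & r < p$p_clear] <- p$anthropic_code
        cur[prev == p$anthropic_code & r < p$p_regrow] <- p$forest_code
        cur[prev == p$natural_code & r < p$p_nat_regrow] <- p$forest_code
        # ground-truth age bookkeeping (consecutive-run rule)
        is_f <- cur == p$forest_code
        started <- prev == p$anthropic_code & is_f & water == 0L
        age <- ifelse(!is_f, 0L,
                      ifelse(age > 0L, age + 1L, ifelse(started, 1L, 0L)))
        ta <- matrix(as.integer(age), p$n_rows, p$n_cols)
        ta[matrix(nodata, p$n_rows, p$n_cols)] <- NA_integer_
        truth[[i - 1L]] <- age_raster(ta, years[i], grid)
      }
      cm <- matrix(as.integer(cur), p$n_rows, p$n_cols)
      cm[matrix(nodata, p$n_rows, p$n_cols)] <- NA_integer_
      rasters[[i]] <- class_raster(cm, years[i], grid)
    }
    names(truth) <- years[-1]
    wm <- matrix(water, p$n_rows, p$n_cols)
    list(stack = annual_stack(rasters),
         water_max = binary_mask(wm, p$start_year, grid),
         truth_ages = truth,
         legend = sim_legend(p))
  })
}

#' Count engine/ground-truth age mismatches
#'
#' Compares a `regrowth_products` age series with the generator's truth ages
#' over their common years. Zero is the only acceptable result for a correct
#' engine; the function exists so tests (and users replaying a simulation)
#' can assert it.
#'
#' @param products a `regrowth_products` from [run_timeline()].
#' @param truth_ages list of [age_raster()] named by year (from
#'   [generate_stack()]).
#' @return integer count of (pixel, year) disagreements over common years
#'   (cells that are nodata in either source are skipped).
#' @export
truth_check <- function(products, truth_ages) {
  common <- intersect(names(products$ages), names(truth_ages))
  if (!length(common)) stopf("no overlapping years between engine and truth ages")
  mismatches <- 0L
  for (k in common) {
    a <- products$ages[[k]]$values
    b <- truth_ages[[k]]$values
    assert_aligned(list(products$ages[[k]], truth_ages[[k]]))
    ok <- !is.na(a) & !is.na(b)
    mismatches <- mismatches + sum(a[ok] != b[ok])
  }
  mismatches
}
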