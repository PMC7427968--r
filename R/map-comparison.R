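# Agreement statistics between two binary secondary-forest maps.
#
# The comparison works on coarse grid cells (e.g. 10 x 10 km blocks of 30-m
# pixels): per cell, the percentage of valid pixels flagged in each map.
# Those per-cell proportions feed (i) a bootstrap of ordinary least-squares
# fits of map A on map B and (ii) Mann-Whitney tests, overall and stratified
# by the reference map's proportion interval.

#' Per-cell secondary-forest proportions for two maps
#'
#' Tiles the shared grid into `cell_size_pixels` x `cell_size_pixels` blocks
#' (edge blocks may be smaller) and computes, per block, the percentage of
#' valid pixels with value 1 in each map. Blocks with no valid pixel in
#' either map are dropped.
#'
#' @param map_a,map_b aligned [binary_mask()] objects (A = map under test,
#'   B = reference map).
#' @param cell_size_pixels block edge length in pixels (e.g. 333 for 10 km
#'   cells on a 30-m grid).
#' @return data frame with columns `cell_id`, `prop_a`, `prop_b` (percent).
#' @export
grid_proportions <- function(map_a, map_b, cell_size_pixels) {
  assert_aligned(list(map_a, map_b))
  cs <- as.integer(cell_size_pixels)
  if (cs < 1L) stopf("cell size must be at least 1 pixel")
  nr <- map_a$grid$n_rows; nc <- map_a$grid$n_cols
  if (cs > max(nr, nc)) stopf("cell size (%d px) exceeds the raster (%d x %d)", cs, nr, nc)
  row_bin <- (seq_len(nr) - 1L) %/% cs
  col_bin <- (seq_len(nc) - 1L) %/% cs
  cell <- outer(row_bin, col_bin, function(r, c) r * (max(col_bin) + 1L) + c)
  prop_of <- function(m) {
    valid <- as.numeric(tapply(!is.na(m$values), cell, sum))
    ones <- as.numeric(tapply(m$values == 1L, cell, sum, na.rm = TRUE))
    list(valid = valid, ones = ones)
  }
  a <- prop_of(map_a); b <- prop_of(map_b)
  keep <- a$valid > 0 & b$valid > 0
  data.frame(cell_id = sort(unique(as.vector(cell)))[keep],
             prop_a = 100 * a$ones[keep] / a$valid[keep],
             prop_b = 100 * b$ones[keep] / b$valid[keep])
}

.ols_stats <- function(x, y) {
  # y ~ x by hand: closed-form slope/intercept keep the bootstrap loop cheap
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sum(resid^2) / syy else NA_real_
  c(r2 = r2, slope = slope, intercept = intercept,
    rmse = sqrt(mean(resid^2)))
}

#' Bootstrap regression comparison of two proportion columns
#'
#' Each iteration draws `ceiling(frac * N)` rows with replacement, fits the
#' ordinary least-squares regression `prop_a = intercept + slope * prop_b`,
#' and records the coefficient of determination, slope, intercept and
#' residual root-mean-square error. Means and standard deviations over all
#' iterations are returned. A drawn sample with zero variance in `prop_b`
#' cannot be fit and is redrawn (counted in `n_degenerate`). Results are
#' reproducible for a fixed seed: one seeded stream feeds the iterations in
#' order.
#'
#' @param table a data frame from [grid_proportions()] (or any with `prop_a`,
#'   `prop_b`), at least 3 rows.
#' @param n_iter number of bootstrap iterations (default 10000).
#' @param frac fraction of rows drawn per iteration (default 0.10).
#' @param seed integer seed for the bootstrap stream.
#' @return an object of class `bootstrap_result`: lists `mean` and `sd` over
#'   the per-iteration `r2`, `slope`, `intercept`, `rmse`, plus `n_iter`,
#'   `frac`, `seed`, `n_cells`, `n_degenerate`.
#' @export
bootstrap_compare <- function(table, n_iter = 10000L, frac = 0.10, seed = 1L) {
  if (nrow(table) < 3L) stopf("need at least 3 cells to bootstrap")
  if (n_iter < 1L) stopf("n_iter must be at least 1")
  if (stats::var(table$prop_a) == 0 || stats::var(table$prop_b) == 0) {
    stopf("a proportion column is constant; regression comparison is undefined")
  }
  n <- nrow(table)
  k <- max(3L, as.integer(ceiling(frac * n)))
  stats <- matrix(NA_real_, n_iter, 4L,
                  dimnames = list(NULL, c("r2", "slope", "intercept", "rmse")))
  n_degenerate <- 0L
  with_local_seed(seed, {
    for (i in seq_len(n_iter)) {
      repeat {
        idx <- sample.int(n, k, replace = TRUE)
        # a constant column leaves the fit (or its R^2) undefined: redraw
        if (stats::var(table$prop_b[idx]) > 0 &&
            stats::var(table$prop_a[idx]) > 0) break
        n_degenerate <- n_degenerate + 1L
      }
      stats[i, ] <- .ols_stats(table$prop_b[idx], table$prop_a[idx])
    }
  })
  structure(list(mean = colMeans(stats), sd = apply(stats, 2, stats::sd),
                 n_iter = n_iter, frac = frac, seed = seed, n_cells = n,
                 n_degenerate = n_degenerate),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d iterations, %.0f%% of %d cells, seed %d\n",
              x$n_iter, 100 * x$frac, x$n_cells, x$seed))
  for (s in names(x$mean)) {
    cat(sprintf("  %-9s %8.4f +/- %.4f\n", s, x$mean[[s]], x$sd[[s]]))
  }
  invisible(x)
}

#' Plain least-squares fit of a proportion table
#'
#' The non-bootstrap fit of `prop_a` on `prop_b` over the full table
#' (equivalently, [bootstrap_compare()] with `frac = 1`, one iteration and
#' sampling disabled).
#'
#' @inheritParams bootstrap_compare
#' @return named numeric `c(r2, slope, intercept, rmse)`.
#' @export
ols_compare <- function(table) {
  .ols_stats(table$prop_b, table$prop_a)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided Mann-Whitney test of `x` against `y`, reporting the U statistic
#' for sample `x` (number of pairs with `x_i > y_j`, ties counted half). The
#' p-value is exact when the samples are tie-free and small
#' (`n_a * n_b <= 10000`), otherwise a normal approximation with tie and
#' continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param x,y non-empty numeric vectors.
#' @return an object of class `mann_whitney_result` with fields `W`, `p`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b`, `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 10000
  if (stats::sd(c(x, y)) == 0) {
    # all values identical: no evidence either way
    W <- length(x) * length(y) / 2
    p <- 1
    method <- "degenerate"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    W <- unname(ht$statistic)
    p <- ht$p.value
    method <- if (exact) "exact" else "normal approximation"
  }
  structure(list(W = W, p = p, n_a = length(x), n_b = length(y),
                 mean_a = mean(x), mean_b = mean(y),
                 sd_a = stats::sd(x), sd_b = stats::sd(y), method = method),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf("<mann_whitney> W = %s, p = %.3g (%s); A: %.2f +/- %.2f (n=%d), B: %.2f +/- %.2f (n=%d)\n",
              format(x$W, big.mark = ","), x$p, x$method,
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}

#' Mann-Whitney tests stratified by reference-map proportion interval
#'
#' Bins the table's rows by `prop_b` (the reference map) into intervals
#' defined by `breaks`: the first interval is `[breaks[1], breaks[2]]`,
#' subsequent ones `(breaks[i], breaks[i+1]]` -- so the conventional
#' 0-10 / 11-20 / ... labels of integer-percent tables are matched without
#' rounding the raw proportions. Each non-empty bin gets a
#' [mann_whitney()] test of its `prop_a` values against its `prop_b` values.
#'
#' @param table a data frame from [grid_proportions()].
#' @param breaks ascending numeric percent bounds, e.g.
#'   `c(0, 10, 20, 30, 40, 80)`.
#' @return data frame with one row per interval: `interval`, `W`, `p`, `n`,
#'   `share_percent`, `mean_a`, `sd_a`, `mean_b`, `sd_b`. Rows with
#'   `prop_b > max(breaks)` are excluded; empty bins have `n = 0` and `NA`
#'   statistics.
#' @export
interval_tests <- function(table, breaks = c(0, 10, 20, 30, 40, 80)) {
  if (is.unsorted(breaks, strictly = TRUE)) stopf("breaks must be strictly ascending")
  keep <- table$prop_b >= breaks[1] & table$prop_b <= breaks[length(breaks)]
  tab <- table[keep, , drop = FALSE]
  bin <- cut(tab$prop_b, breaks = breaks, include.lowest = TRUE, right = TRUE)
  lo <- breaks[-length(breaks)]
  # integer-percent convention: [0,10] prints as 0-10%, (10,20] as 11-20%, ...
  lo_lab <- ifelse(seq_along(lo) > 1 & lo == round(lo), lo + 1, lo)
  labels <- sprintf("%g-%g%%", lo_lab, breaks[-1])
  n_total <- nrow(tab)
  rows <- lapply(seq_along(labels), function(i) {
    sel <- as.integer(bin) == i
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(interval = labels[i], W = NA_real_, p = NA_real_,
                        n = 0L, share_percent = 0, mean_a = NA_real_,
                        sd_a = NA_real_, mean_b = NA_real_, sd_b = NA_real_))
    }
    mw <- mann_whitney(tab$prop_a[sel], tab$prop_b[sel])
    data.frame(interval = labels[i], W = mw$W, p = mw$p, n = n,
               share_percent = 100 * n / n_total,
               mean_a = mw$mean_a, sd_a = mw$sd_a,
               mean_b = mw$mean_b, sd_b = mw$sd_b)
  })
  do.call(rbind, rows)
}
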