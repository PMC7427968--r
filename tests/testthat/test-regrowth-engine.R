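# Step recurrences and the timeline driver, checked against the per-pixel
# oracle, the generator's ground truth, and the literal sum/threshold/multiply
# formulation of the extent rule.

test_that("increment requires forest now, anthropic before, and dry land", {
  g <- tiny_grid(1, 4)
  f <- mk_mask(matrix(c(1L, 1L, 1L, 0L), 1, 4), 1991L, g)
  a <- mk_mask(matrix(c(1L, 0L, 1L, 1L), 1, 4), 1990L, g)
  w <- mk_mask(matrix(c(0L, 0L, 1L, 0L), 1, 4), 1990L, g)
  inc <- increment(f, a, w)
  expect_identical(inc$values, matrix(c(1L, 0L, 0L, 0L), 1, 4))
  expect_identical(increment(f, a)$values, matrix(c(1L, 0L, 1L, 0L), 1, 4))
  expect_error(increment(f, mk_mask(matrix(1L, 1, 4), 1985L, g)), "consecutive")
})

test_that("extent_step carries survivors, adds increments, drops deforested", {
  g <- tiny_grid(1, 3)
  ep <- mk_mask(matrix(c(1L, 1L, 0L), 1, 3), 1990L, g)
  ic <- mk_mask(matrix(c(0L, 0L, 1L), 1, 3), 1991L, g)
  f <- mk_mask(matrix(c(1L, 0L, 1L), 1, 3), 1991L, g)
  expect_identical(extent_step(ep, ic, f)$values, matrix(c(1L, 0L, 1L), 1, 3))
})

test_that("loss_step flags extent pixels that stop being forest", {
  g <- tiny_grid(1, 3)
  ep <- mk_mask(matrix(c(1L, 1L, 0L), 1, 3), 1990L, g)
  f <- mk_mask(matrix(c(0L, 1L, 0L), 1, 3), 1991L, g)
  expect_identical(loss_step(ep, f)$values, matrix(c(1L, 0L, 0L), 1, 3))
  all_forest <- mk_mask(matrix(1L, 1, 3), 1991L, g)
  expect_identical(sum(loss_step(ep, all_forest)$values), 0L)
})

test_that("age_step accumulates inside the extent and resets on clearing", {
  g <- tiny_grid(1, 3)
  ap <- mk_age(matrix(c(4L, 4L, 0L), 1, 3), 1990L, g)
  ex <- mk_mask(matrix(c(1L, 0L, 0L), 1, 3), 1991L, g)
  f <- mk_mask(matrix(c(1L, 0L, 1L), 1, 3), 1991L, g)
  # pixel 1: ages on; pixel 2: cleared -> 0; pixel 3: old-growth stays 0
  expect_identical(age_step(ap, ex, f)$values, matrix(c(5L, 0L, 0L), 1, 3))
})

test_that("timeline reproduces hand-computed pixel histories", {
  lg <- legend_config()
  # pasture,forest,forest,pasture,pasture,forest,forest over 1985-1991
  prod <- run_timeline(pixel_stack(c(15L, 3L, 3L, 15L, 15L, 3L, 3L)), lg)
  expect_identical(pixel_ages(prod), c(1L, 2L, 0L, 0L, 1L, 2L))
  # always forest: old-growth never ages
  prod2 <- run_timeline(pixel_stack(rep(3L, 7)), lg)
  expect_identical(pixel_ages(prod2), rep(0L, 6))
  # savanna -> forest: natural prior cover never triggers an increment
  prod3 <- run_timeline(pixel_stack(c(4L, 3L, 3L)), lg)
  expect_identical(pixel_ages(prod3), c(0L, 0L))
  expect_identical(names(prod$increments)[1], "1986")
  expect_identical(names(prod$losses)[1], "1987")
})

test_that("pixel_oracle matches its stated scan rule", {
  lg <- legend_config()
  expect_identical(pixel_oracle(c(15L, 3L, 3L), lg), c(1L, 2L))
  expect_identical(pixel_oracle(c(15L, 3L, 15L, 3L), lg), c(1L, 0L, 1L))
  expect_identical(pixel_oracle(c(15L, 3L, 3L), lg, water_flag = 1L), c(0L, 0L))
  expect_identical(pixel_oracle(c(4L, 3L, 3L), lg), c(0L, 0L))
  expect_error(pixel_oracle(3L, lg), "two years")
})

test_that("a new anthropic->forest transition restarts age immediately", {
  lg <- legend_config()
  prod <- run_timeline(pixel_stack(c(15L, 3L, 15L, 3L, 3L)), lg)
  expect_identical(pixel_ages(prod), c(1L, 0L, 1L, 2L))
})

test_that("water-masked pixels never enter the secondary-forest pool", {
  sim <- generate_stack(sim_params(n_rows = 15L, n_cols = 15L,
                                   end_year = 2000L, water_frac = 0.3,
                                   seed = 5L))
  prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
  wet <- sim$water_max$values == 1L
  for (k in names(prod$ages)) {
    expect_identical(sum(prod$ages[[k]]$values[wet], na.rm = TRUE), 0L)
    expect_identical(sum(prod$extents[[k]]$values[wet], na.rm = TRUE), 0L)
  }
})

test_that("engine ages equal the per-pixel oracle on random stacks", {
  for (seed in 1:8) {
    sim <- generate_stack(random_sim_params(seed, nr = 12L, nc = 12L,
                                            n_years = 15L))
    prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
    engine <- ages_matrix(prod)
    codes <- vapply(sim$stack$rasters, function(r) as.vector(r$values),
                    integer(144))
    wflag <- as.vector(sim$water_max$values)
    oracle <- t(vapply(seq_len(144), function(px) {
      pixel_oracle(codes[px, ], sim$legend, wflag[px])
    }, integer(ncol(codes) - 1L)))
    expect_identical(engine, oracle)
  }
})

test_that("pixel counts obey the extent conservation identity", {
  for (seed in 11:16) {
    sim <- generate_stack(random_sim_params(seed, nr = 15L, nc = 15L,
                                            n_years = 12L))
    prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
    expect_identical(max(abs(conservation_table(prod)$residual)), 0L)
  }
})

test_that("increment pixels were outside the previous extent", {
  sim <- generate_stack(random_sim_params(21L, nr = 15L, nc = 15L,
                                          n_years = 12L))
  prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
  yrs <- as.integer(names(prod$extents))
  for (y in yrs[-1]) {
    overlap <- prod$increments[[as.character(y)]]$values *
      prod$extents[[as.character(y - 1L)]]$values
    expect_identical(sum(overlap, na.rm = TRUE), 0L)
  }
})

test_that("extent flags exactly the pixels with positive age", {
  sim <- generate_stack(random_sim_params(22L, nr = 15L, nc = 15L,
                                          n_years = 12L))
  prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
  for (k in names(prod$extents)) {
    expect_identical(prod$extents[[k]]$values == 1L,
                     prod$ages[[k]]$values >= 1L)
  }
})

test_that("ages never exceed the observable record and the bound is attained", {
  sim <- generate_stack(random_sim_params(23L, nr = 15L, nc = 15L,
                                          n_years = 12L))
  prod <- run_timeline(sim$stack, sim$legend, sim$water_max)
  for (k in names(prod$ages)) {
    expect_lte(max(prod$ages[[k]]$values, na.rm = TRUE),
               as.integer(k) - prod$start_year)
  }
  # a pixel that increments in the first transition year and stays forest
  # attains the bound every year
  prod1 <- run_timeline(pixel_stack(c(15L, rep(3L, 9))), legend_config())
  expect_identical(pixel_ages(prod1), 1:9)
})

test_that("after any non-forest year a pixel's age is zero regardless of history", {
  lg <- legend_config()
  set.seed(41)
  for (i in 1:30) {
    codes <- sample(c(3L, 15L, 4L), 12, replace = TRUE)
    ages <- pixel_oracle(codes, lg)
    nonforest <- which(codes[-1] != 3L)
    expect_true(all(ages[nonforest] == 0L))
  }
})

test_that("the OR/AND extent rule equals the literal sum-threshold-multiply procedure", {
  set.seed(42)
  g <- tiny_grid(8, 8)
  for (rep in 1:5) {
    n_years <- 10L
    incs <- list(); fors <- list()
    for (i in seq_len(n_years)) {
      fors[[i]] <- matrix(rbinom(64, 1, 0.6), 8, 8)
      incs[[i]] <- matrix(rbinom(64, 1, 0.2), 8, 8) * fors[[i]]
    }
    lit <- literal_extents(incs, fors)
    ext_prev <- mk_mask(incs[[1]] * fors[[1]], 2000L, g)
    for (i in 2:n_years) {
      ext <- extent_step(ext_prev,
                         mk_mask(incs[[i]], 2000L + i - 1L, g),
                         mk_mask(fors[[i]], 2000L + i - 1L, g))
      expect_identical(ext$values, lit[[i]])
      ext_prev <- ext
    }
  }
})

test_that("nodata in any input year voids the pixel in every product", {
  g <- tiny_grid(1, 2)
  codes <- list(c(15L, 15L), c(3L, 3L), c(NA, 3L), c(3L, 3L))
  st <- annual_stack(lapply(seq_along(codes), function(i) {
    class_raster(matrix(codes[[i]], 1, 2), 1989L + i, g)
  }))
  prod <- run_timeline(st, legend_config())
  for (k in names(prod$ages)) {
    expect_true(is.na(prod$ages[[k]]$values[1, 1]))
    expect_false(is.na(prod$ages[[k]]$values[1, 2]))
  }
})
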