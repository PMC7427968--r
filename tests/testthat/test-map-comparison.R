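test_that("grid_proportions computes per-cell percentages and drops empty cells", {
  g <- tiny_grid(10, 10)
  a <- matrix(0L, 10, 10); a[1:7] <- 1L       # 7 ones in the single 10x10 cell
  pa <- grid_proportions(mk_mask(a, 2000L, g), mk_mask(matrix(0L, 10, 10), 2000L, g),
                         cell_size_pixels = 10L)
  expect_equal(nrow(pa), 1L)
  expect_equal(pa$prop_a, 7)
  expect_equal(pa$prop_b, 0)

  set.seed(61)
  m <- matrix(rbinom(400, 1, 0.3), 20, 20)
  same <- grid_proportions(mk_mask(m, 2000L, tiny_grid(20, 20)),
                           mk_mask(m, 2000L, tiny_grid(20, 20)), 5L)
  expect_equal(same$prop_a, same$prop_b)
  expect_equal(nrow(same), 16L)

  # an all-nodata cell disappears
  m2 <- m; m2[1:5, 1:5] <- NA
  dropped <- grid_proportions(mk_mask(m2, 2000L, tiny_grid(20, 20)),
                              mk_mask(m2, 2000L, tiny_grid(20, 20)), 5L)
  expect_equal(nrow(dropped), 15L)
  expect_error(grid_proportions(mk_mask(m, 2000L, tiny_grid(20, 20)),
                                mk_mask(m, 2000L, tiny_grid(20, 20)), 50L),
               "exceeds")
})

test_that("bootstrap on identical maps is the exact identity fit", {
  set.seed(62)
  tab <- data.frame(prop_a = runif(200, 0, 40))
  tab$prop_b <- tab$prop_a
  res <- bootstrap_compare(tab, n_iter = 100L, frac = 0.1, seed = 9L)
  expect_equal(res$mean[["r2"]], 1)
  expect_equal(res$mean[["slope"]], 1)
  expect_equal(res$mean[["intercept"]], 0, tolerance = 1e-12)
  expect_equal(res$mean[["rmse"]], 0, tolerance = 1e-12)
  expect_true(all(res$sd < 1e-12))

  doubled <- data.frame(prop_a = 2 * tab$prop_a, prop_b = tab$prop_b)
  res2 <- bootstrap_compare(doubled, n_iter = 50L, frac = 0.2, seed = 9L)
  expect_equal(res2$mean[["slope"]], 2)
  expect_equal(res2$mean[["r2"]], 1)
})

test_that("bootstrap is bit-reproducible for a fixed seed", {
  set.seed(63)
  tab <- data.frame(prop_b = runif(150, 0, 30))
  tab$prop_a <- tab$prop_b + rnorm(150)
  r1 <- bootstrap_compare(tab, n_iter = 50L, seed = 7L)
  r2 <- bootstrap_compare(tab, n_iter = 50L, seed = 7L)
  expect_identical(r1, r2)
  r3 <- bootstrap_compare(tab, n_iter = 50L, seed = 8L)
  expect_false(identical(r1$mean, r3$mean))
})

test_that("bootstrap recovers the generating residual noise level", {
  sigma <- 2
  tab <- with_local_seed(64L, {
    b <- runif(1000, 0, 50)
    data.frame(prop_a = b + rnorm(1000, sd = sigma), prop_b = b)
  })
  res <- bootstrap_compare(tab, n_iter = 200L, frac = 0.10, seed = 3L)
  expect_lt(abs(res$mean[["rmse"]] - sigma), 3 * res$sd[["rmse"]])
  expect_equal(res$mean[["slope"]], 1, tolerance = 0.05)
})

test_that("full-table fit matches the closed-form least-squares oracle", {
  set.seed(65)
  tab <- data.frame(prop_b = runif(80, 0, 20))
  tab$prop_a <- 1.5 + 0.7 * tab$prop_b + rnorm(80)
  fit <- ols_compare(tab)
  lmfit <- lm(prop_a ~ prop_b, data = tab)
  expect_equal(fit[["slope"]], unname(coef(lmfit)[2]))
  expect_equal(fit[["intercept"]], unname(coef(lmfit)[1]))
  expect_equal(fit[["r2"]], summary(lmfit)$r.squared)
  expect_equal(fit[["rmse"]], sqrt(mean(residuals(lmfit)^2)))
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$W, 0)
  expect_equal(mann_whitney(c(10), c(1))$W, 1)
  x <- c(1, 2, 3); expect_equal(mann_whitney(x, x)$W, length(x)^2 / 2)
  set.seed(66)
  for (i in 1:25) {
    n_a <- sample(1:8, 1); n_b <- sample(1:8, 1)
    x <- sample(1:12, n_a, replace = TRUE)
    y <- sample(1:12, n_b, replace = TRUE)
    mw <- mann_whitney(x, y)
    expect_equal(mw$W, brute_force_U(x, y))
    # complement identity
    expect_equal(mw$W + mann_whitney(y, x)$W, n_a * n_b)
  }
})

test_that("Mann-Whitney p-values agree with the reference implementation", {
  set.seed(67)
  x <- rnorm(40); y <- rnorm(35, mean = 0.5)
  mw <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mw$p, ref$p.value)
  # large/tied samples: corrected normal approximation
  xt <- sample(1:5, 200, replace = TRUE); yt <- sample(1:5, 150, replace = TRUE)
  expect_equal(mann_whitney(xt, yt)$p,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value)
  ident <- mann_whitney(rep(2, 5), rep(2, 7))
  expect_equal(ident$p, 1)
  expect_equal(ident$W, 5 * 7 / 2)
})

test_that("interval tests bin by the reference map and report shares", {
  set.seed(68)
  b <- runif(600, 0, 60)
  tab <- data.frame(prop_a = pmax(b - 1, 0), prop_b = b)
  res <- interval_tests(tab, breaks = c(0, 10, 20, 30, 40, 80))
  expect_equal(sum(res$n), 600L)
  expect_equal(sum(res$share_percent), 100)
  expect_identical(res$interval[1:2], c("0-10%", "11-20%"))
  # single bin covering everything reduces to the overall test
  whole <- interval_tests(tab, breaks = c(0, 100))
  overall <- mann_whitney(tab$prop_a, tab$prop_b)
  expect_equal(whole$W, overall$W)
  expect_equal(whole$p, overall$p)
  expect_equal(whole$n, 600L)
})

test_that("a stochastically smaller map is detected in every interval", {
  tab <- with_local_seed(69L, {
    b <- c(runif(500, 2, 10), runif(500, 12, 20), runif(500, 22, 30))
    data.frame(prop_a = pmax(b - 1 + rnorm(1500, sd = 0.2), 0), prop_b = b)
  })
  res <- interval_tests(tab, breaks = c(0, 10, 20, 30))
  expect_true(all(res$p < 0.01))
  expect_true(all(res$mean_a < res$mean_b))
  # identical single pairs give p = 1 per bin
  tab1 <- data.frame(prop_a = c(5, 15), prop_b = c(5, 15))
  res1 <- interval_tests(tab1, breaks = c(0, 10, 20))
  expect_equal(res1$p, c(1, 1))
})
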