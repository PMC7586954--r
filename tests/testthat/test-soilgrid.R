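test_that("variogram fitting recovers a generated field's structure", {
  field <- gen_soil_field(n_locations = 200, range_m = 30, sill = 0.0025,
                          nugget = 0.00025, seed = 1)
  top <- field[field$depth_top == 0, ]
  vg <- fit_variogram(top, "clay", model = "exponential")
  # range recovery is inherently noisy; within 50%
  expect_gt(vg$range, 15)
  expect_lt(vg$range, 45)
  expect_gt(vg$partial_sill, 0)
  # semivariance is nondecreasing in lag
  h <- seq(0, 200, by = 1)
  expect_true(all(diff(semivariance(vg, h)) >= -1e-12))
})

test_that("variogram fitting rejects or degrades degenerate inputs", {
  few <- data.frame(x = c(0, 10), y = c(0, 0), clay = c(0.2, 0.3))
  expect_error(fit_variogram(few, "clay"), "at least 10")
  const <- data.frame(x = runif(20, 0, 100), y = runif(20, 0, 50),
                      clay = rep(0.25, 20))
  expect_warning(vg <- fit_variogram(const, "clay"), "zero-variance")
  expect_equal(vg$nugget, 0)
  expect_equal(vg$partial_sill, 0)
})

test_that("kriging weights solve the ordinary-kriging system (hand oracle)", {
  s <- data.frame(x = c(0, 10, 4), y = c(0, 0, 6), clay = c(0.2, 0.3, 0.25))
  vg <- structure(list(model = "exponential", nugget = 0.01,
                       partial_sill = 0.05, range = 8),
                  class = "variogram_model")
  blk <- data.frame(xmin = 3, xmax = 3, ymin = 2, ymax = 2)  # a point
  kr <- block_krige(s, vg, "clay", blk)
  # independent linear solve of the 4x4 system
  gmat <- function(h) ifelse(h <= 0, 0, 0.01 + 0.05 * (1 - exp(-h / 8)))
  D <- as.matrix(dist(s[, c("x", "y")]))
  A <- rbind(cbind(gmat(D), 1), c(1, 1, 1, 0))
  d0 <- sqrt((s$x - 3)^2 + (s$y - 2)^2)
  rhs <- c(gmat(d0), 1)
  lam <- solve(A, rhs)
  expect_equal(as.numeric(kr$weights), unname(lam[1:3]), tolerance = 1e-10)
  expect_equal(kr$predictions$pred, sum(lam[1:3] * s$clay), tolerance = 1e-10)
})

test_that("kriging is exact at sample sites when the nugget is zero", {
  set.seed(31)
  s <- data.frame(x = runif(15, 0, 100), y = runif(15, 0, 60))
  s$clay <- 0.2 + 0.1 * sin(s$x / 20) * cos(s$y / 15)
  vg <- structure(list(model = "exponential", nugget = 0,
                       partial_sill = 0.01, range = 25),
                  class = "variogram_model")
  blk <- data.frame(xmin = s$x, xmax = s$x, ymin = s$y, ymax = s$y)
  kr <- block_krige(s, vg, "clay", blk)
  expect_lt(max(abs(kr$predictions$pred - s$clay)), 1e-8)
  expect_true(all(kr$predictions$var >= 0))
})

test_that("kriging weights sum to one on every system", {
  set.seed(32)
  s <- data.frame(x = runif(12, 0, 80), y = runif(12, 0, 40),
                  clay = runif(12, 0.15, 0.35))
  vg <- structure(list(model = "spherical", nugget = 0.002,
                       partial_sill = 0.01, range = 30),
                  class = "variogram_model")
  blk <- data.frame(xmin = c(0, 20, 60), xmax = c(10, 30, 70),
                    ymin = c(0, 10, 20), ymax = c(10, 20, 30))
  kr <- block_krige(s, vg, "clay", blk, discretization = 4)
  expect_equal(rowSums(kr$weights), rep(1, 3), tolerance = 1e-10)
})

test_that("a single sample predicts itself everywhere (unbiasedness)", {
  s <- data.frame(x = 5, y = 5, clay = 0.27)
  vg <- structure(list(model = "exponential", nugget = 0.01,
                       partial_sill = 0.05, range = 10),
                  class = "variogram_model")
  blk <- data.frame(xmin = c(0, 50), xmax = c(10, 60), ymin = c(0, 0),
                    ymax = c(10, 10))
  kr <- suppressWarnings(block_krige(s, vg, "clay", blk))
  expect_equal(kr$predictions$pred, c(0.27, 0.27))
})

test_that("block prediction equals the mean of its point predictions", {
  set.seed(33)
  s <- data.frame(x = runif(10, 0, 50), y = runif(10, 0, 50),
                  clay = runif(10, 0.1, 0.4))
  vg <- structure(list(model = "exponential", nugget = 0.001,
                       partial_sill = 0.02, range = 15),
                  class = "variogram_model")
  blk <- data.frame(xmin = 10, xmax = 20, ymin = 10, ymax = 20)
  kr <- block_krige(s, vg, "clay", blk, discretization = 3)
  # point predictions on the same 3x3 midpoint grid
  gx <- 10 + (1:3 - 0.5) / 3 * 10
  pts <- expand.grid(x = gx, y = gx)
  kp <- block_krige(s, vg, "clay",
                    data.frame(xmin = pts$x, xmax = pts$x, ymin = pts$y,
                               ymax = pts$y))
  expect_equal(kr$predictions$pred, mean(kp$predictions$pred),
               tolerance = 1e-9)
})

test_that("cell aggregation renormalizes and selects clay extremes", {
  # 10 identical plots average to themselves
  pv <- data.frame(plot_id = 1:10, clay = 0.1, sand = 0.6, silt = 0.3)
  ly <- data.frame(plot_id = 1:10, cell_id = "c1")
  agg <- aggregate_and_select_cells(pv, ly)
  expect_equal(agg$cells$clay, 0.1)

  # 44 cells of 1 plot each, distinct clay: ceil(0.1 * 44) = 5 per tail
  set.seed(34)
  clay <- runif(44, 0.1, 0.4)
  pv44 <- data.frame(plot_id = 1:44, clay = clay, sand = 0.9 - clay,
                     silt = 0.1)
  ly44 <- data.frame(plot_id = 1:44, cell_id = paste0("c", 1:44))
  agg44 <- aggregate_and_select_cells(pv44, ly44)
  expect_equal(nrow(agg44$high_clay), ceiling(0.1 * 44))
  expect_equal(nrow(agg44$low_clay), ceiling(0.1 * 44))
  expect_true(all(agg44$high_clay$clay >= max(agg44$low_clay$clay)))

  # unassigned plot is an error
  ly_bad <- ly44[-1, ]
  expect_error(aggregate_and_select_cells(pv44, ly_bad), "unassigned")
})

test_that("representative texture applies the cell-averaging rule", {
  cells <- data.frame(clay = c(0.27, 0.286), sand = c(0.55, 0.534),
                      silt = c(0.18, 0.18))
  rep_tx <- representative_texture(cells)
  expect_equal(unname(rep_tx["clay"]), 0.278, tolerance = 1e-9)
  expect_equal(sum(rep_tx), 1, tolerance = 1e-12)
})

test_that("soil sample IO validates closure and depth intervals", {
  f <- gen_soil_field(n_locations = 12, seed = 8)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(x_m = f$x, y_m = f$y, depth_top_cm = f$depth_top,
               depth_bottom_cm = f$depth_bottom, clay = f$clay,
               sand = f$sand, silt = f$silt),
    path, row.names = FALSE)
  s <- read_soil_samples(path)
  expect_equal(nrow(s), nrow(f))
  expect_true(all(abs(s$clay + s$sand + s$silt - 1) < 1e-6))
})
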