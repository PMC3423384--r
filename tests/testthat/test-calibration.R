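make_precip <- function() {
  g <- grid_spec(10, 10, lon_origin = -100, lat_origin = 50,
                 cell_size_deg = 0.5)
  raster_surface(g, matrix(seq(-140, -40, length.out = 10), 10, 10))
}

test_that("exact linear data is recovered exactly", {
  precip <- make_precip()
  cal <- exact_line_samples(precip, c(1, 23, 45, 67, 89),
                            intercept = -25, slope = 1.0)
  m <- fit_calibration(cal, precip, "ASY")
  expect_equal(m$intercept_permil, -25, tolerance = 1e-9)
  expect_equal(m$slope, 1.0, tolerance = 1e-9)
  expect_equal(m$residual_sd_permil, 0, tolerance = 1e-9)
  expect_equal(m$n_samples, 5L)
})

test_that("seeded noisy fit matches the closed-form OLS oracle and brackets truth", {
  withr::local_seed(101)
  precip <- make_precip()
  x_all_for_ci <- surface_values(precip)
  cells <- sample.int(100, 200, replace = TRUE)
  x <- surface_values(precip, cells)
  b0 <- -20; b1 <- 0.9; sigma <- 8
  y <- b0 + b1 * x + rnorm(200, 0, sigma)
  cc <- cell_centers(precip$grid)[cells, ]
  cal <- tibble::tibble(sample_id = as.character(1:200), age_class = "ASY",
                        lon = cc$lon, lat = cc$lat, d2hf = y)
  m <- fit_calibration(cal, precip, "ASY")

  # longhand OLS oracle
  slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  int_hat <- mean(y) - slope_hat * mean(x)
  rss <- sum((y - int_hat - slope_hat * x)^2)
  expect_equal(m$slope, slope_hat, tolerance = 1e-9)
  expect_equal(m$intercept_permil, int_hat, tolerance = 1e-9)
  expect_equal(m$residual_sd_permil, sqrt(rss / 198), tolerance = 1e-9)

  expect_gte(m$residual_sd_permil, 6.5)
  expect_lte(m$residual_sd_permil, 9.5)

  # the 95% CIs bracket the generating values at near-nominal rates over
  # replicates (a single realization misses ~5% of the time by design)
  hits <- vapply(1:40, function(s) {
    set.seed(300 + s)
    xr <- x_all_for_ci[sample.int(100, 200, replace = TRUE)]
    yr <- b0 + b1 * xr + rnorm(200, 0, sigma)
    ci <- confint(lm(yr ~ xr))
    ci[1, 1] <= b0 && b0 <= ci[1, 2] && ci[2, 1] <= b1 && b1 <= ci[2, 2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("age classes are fitted independently", {
  precip <- make_precip()
  asy <- exact_line_samples(precip, c(1, 23, 45, 67, 89), -20, 0.9, "ASY")
  sy <- exact_line_samples(precip, c(11, 33, 55, 77, 99), -25, 0.95, "SY")
  both <- dplyr::bind_rows(asy, sy)
  models <- fit_calibrations(both, precip)
  expect_named(models, c("SY", "ASY"), ignore.order = TRUE)
  expect_equal(models$ASY$slope, 0.9, tolerance = 1e-9)
  expect_equal(models$SY$slope, 0.95, tolerance = 1e-9)
  expect_equal(models$SY$intercept_permil, -25, tolerance = 1e-9)
})

test_that("unusable inputs raise the specified errors", {
  precip <- make_precip()
  few <- exact_line_samples(precip, c(1, 2), -20, 0.9)
  expect_error(fit_calibration(few, precip, "ASY"), "insufficient")
  # all samples in one cell: zero predictor variance
  flat <- exact_line_samples(precip, c(5, 5, 5, 5), -20, 0.9)
  expect_error(fit_calibration(flat, precip, "ASY"), "degenerate")
  # samples off the range mask don't count
  mask <- matrix(TRUE, 10, 10); mask[, 1:5] <- FALSE
  masked <- raster_surface(precip$grid, precip$values, mask)
  west <- exact_line_samples(masked, c(1, 11, 21, 31), -20, 0.9)
  west$lon <- cell_centers(precip$grid)$lon[1] # all in masked column 1
  expect_error(fit_calibration(west, masked, "ASY"), "insufficient")
})

test_that("refitting on the model's own noiseless predictions is a fixed point", {
  precip <- make_precip()
  m <- fit_calibration(
    exact_line_samples(precip, c(2, 34, 56, 78, 91), -18.5, 0.87), precip,
    "ASY"
  )
  surf <- predict_feather_surface(m, precip)
  cells <- c(5, 15, 25, 35, 45, 55)
  cc <- cell_centers(precip$grid)[cells, ]
  again <- tibble::tibble(
    sample_id = as.character(cells), age_class = "ASY",
    lon = cc$lon, lat = cc$lat, d2hf = surface_values(surf, cells)
  )
  m2 <- fit_calibration(again, precip, "ASY")
  expect_equal(m2$intercept_permil, m$intercept_permil, tolerance = 1e-9)
  expect_equal(m2$slope, m$slope, tolerance = 1e-9)
  expect_lte(m2$residual_sd_permil, 1e-9)
})

test_that("estimates converge to truth as sample size grows", {
  # root-n consistency of the slope: with a 100-fold sample-size jump the
  # sampling SD shrinks 10-fold, so the large-n fit beats the small-n fit
  # with probability 2/pi * atan(10) ~ 0.937 per replicate; we require the
  # win rate to clear a 3-sigma binomial lower bound of that rate, and the
  # aggregate error to shrink by close to the theoretical factor
  precip <- make_precip()
  x_all <- surface_values(precip)
  b0 <- -20; b1 <- 0.9; sigma <- 8
  errs <- withr::with_seed(202, {
    vapply(1:100, function(rep) {
      vapply(c(50, 5000), function(n) {
        x <- x_all[sample.int(100, n, replace = TRUE)]
        y <- b0 + b1 * x + rnorm(n, 0, sigma)
        sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        abs(sl - b1)
      }, numeric(1))
    }, numeric(2))
  })
  expect_gte(mean(errs[2, ] < errs[1, ]), 0.86)
  expect_lt(mean(errs[2, ]), mean(errs[1, ]) / 5)
})

test_that("predict_feather_surface is the affine cell-wise map", {
  precip <- make_precip()
  mask <- matrix(TRUE, 10, 10); mask[3, ] <- FALSE
  masked <- raster_surface(precip$grid, precip$values, mask)

  ident <- new_model_for_test(0, 1)
  expect_equal(predict_feather_surface(ident, masked)$values, masked$values)

  m <- new_model_for_test(-20, 0.9)
  out <- predict_feather_surface(m, masked)
  # hand arithmetic: -20 + 0.9 * (-100) = -110
  one_cell <- raster_surface(grid_spec(1, 1, 0, 0, 1), -100)
  expect_equal(surface_values(predict_feather_surface(m, one_cell)), -110)
  # mask preserved
  expect_equal(out$range_mask, mask)
  expect_true(all(is.na(out$values[3, ])))
  # affine in the input, cell-wise
  scaled <- raster_surface(precip$grid, 2 * precip$values, mask)
  expect_equal(predict_feather_surface(m, scaled)$values,
               -20 + 0.9 * 2 * precip$values * ifelse(mask, 1, NA))
})

test_that("calibration models serialize to JSON and back", {
  precip <- make_precip()
  m <- fit_calibration(
    exact_line_samples(precip, c(2, 34, 56, 78, 91), -18.5, 0.87), precip,
    "ASY"
  )
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(m, f)
  m2 <- read_calibration_json(f)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
  # broom-style accessors
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "slope"], m$slope)
  expect_equal(glance(m)$n_samples, m$n_samples)
})
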