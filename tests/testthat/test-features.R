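test_that("relative humidity follows the Magnus form", {
  # identical dew point and air temperature saturate exactly
  expect_identical(relative_humidity(15, 15), 100)
  for (t in c(-30, 0, 12.3, 40)) expect_equal(relative_humidity(t, t), 100)
  # independent evaluation in log space
  log_rh <- function(td, tm)
    100 * exp(17.625 * td / (243.04 + td) - 17.625 * tm / (243.04 + tm))
  expect_equal(relative_humidity(0, 20), log_rh(0, 20))
  expect_equal(round(relative_humidity(0, 20), 1), 26.2)
  # supersaturation is allowed, not clipped
  expect_gt(relative_humidity(25, 20), 100)
  # monotone: increasing in dew point, decreasing in air temperature
  td <- seq(-40, 40, length.out = 100)
  expect_true(all(diff(relative_humidity(td, 45)) > 0))
  expect_true(all(diff(relative_humidity(-41, td)) < 0))
  expect_error(relative_humidity(-250, 10), "-243.04")
})

test_that("scalar covariate operations match their definitions", {
  expect_identical(daily_precip_total(1), 24)
  expect_identical(daily_precip_total(0), 0)
  expect_identical(daily_precip_total(2.5), 60)
  expect_error(daily_precip_total(-0.1), "negative")
  expect_equal(wind_magnitude(3, 4), 5)
  expect_equal(wind_magnitude(0, 0), 0)
  expect_equal(wind_magnitude(-3, 4), 5)
  expect_equal(temperature_range(30, 20), 10)
  expect_equal(temperature_range(5, 5), 0)
  expect_warning(r <- temperature_range(19.9, 20.0), "clamped")
  expect_equal(r, 0)
})

test_that("derive_all computes the five covariates on a known cube", {
  grid <- grid_spec(0, 0.25, 0, 0.25)
  cube <- climate_cube(grid, as.Date("2020-06-01"), list(
    tmean = array(20, c(1, 1, 1)), tmax = array(26, c(1, 1, 1)),
    tmin = array(16, c(1, 1, 1)), dewpoint = array(10, c(1, 1, 1)),
    precip_hourly = array(0.5, c(1, 1, 1)),
    uwind = array(3, c(1, 1, 1)), vwind = array(-4, c(1, 1, 1))))
  d <- derive_all(cube)
  expect_s3_class(d, "derived_cube")
  expect_identical(d$dates, cube$dates)
  expect_equal(d$vars$trange[1, 1, 1], 10)
  expect_equal(d$vars$tmean[1, 1, 1], 20)
  expect_equal(d$vars$rh[1, 1, 1], relative_humidity(10, 20))
  expect_equal(d$vars$ptot[1, 1, 1], 12)
  expect_equal(d$vars$wspd[1, 1, 1], 5)
  # negative precipitation artifacts clamp to zero with a count
  cube$vars$precip_hourly[1, 1, 1] <- -0.2
  d2 <- derive_all(cube)
  expect_equal(d2$vars$ptot[1, 1, 1], 0)
  expect_equal(attr(d2, "n_precip_clamped"), 1)
})

test_that("derive_all commutes with cell subsetting", {
  w <- generate_climate(world_config(n_lat = 6, n_lon = 8, years = 1, seed = 3))
  d_full <- derive_all(w$cube)
  # crop to rows 2:4, cols 3:6, then derive
  sub_vars <- lapply(w$cube$vars, function(a) a[2:4, 3:6, , drop = FALSE])
  gsub <- grid_spec(w$cube$grid$lat_min + w$cube$grid$cell_size_lat,
                    w$cube$grid$lat_min + 4 * w$cube$grid$cell_size_lat,
                    w$cube$grid$lon_min + 2 * w$cube$grid$cell_size_lon,
                    w$cube$grid$lon_min + 6 * w$cube$grid$cell_size_lon,
                    w$cube$grid$cell_size_lat, w$cube$grid$cell_size_lon)
  d_crop <- derive_all(climate_cube(gsub, w$cube$dates, sub_vars))
  for (v in derived_variables())
    expect_equal(d_crop$vars[[v]], d_full$vars[[v]][2:4, 3:6, , drop = FALSE])
})

test_that("assemble_sequence flattens day-major and matches a naive oracle", {
  cube <- tiny_derived_cube()
  # seq_len = 1: previous day's five variables in canonical order
  v <- assemble_sequence(cube, cell = 5, date = cube$dates[4], seq_len = 1)
  expect_length(v, 5)
  expect_equal(v, vapply(seq_len(5), function(k) 5 + 3 / 100 + k / 1000,
                         numeric(1)))
  # randomized agreement with the per-day lookup oracle
  set.seed(4)
  for (i in 1:20) {
    cell <- sample(n_cells(cube$grid), 1)
    L <- sample(1:5, 1)
    date <- cube$dates[sample((L + 1):length(cube$dates), 1)]
    expect_equal(assemble_sequence(cube, cell, date, L),
                 oracle_sequence(cube, cell, date, L))
  }
  # observation day itself is excluded
  v3 <- assemble_sequence(cube, 1, cube$dates[3], 2)
  expect_false(any(abs(v3 - (1 + 3 / 100 + 1 / 1000)) < 1e-12))
  expect_error(assemble_sequence(cube, 1, cube$dates[1], 1), "insufficient history")
  expect_error(assemble_sequence(cube, 1, cube$dates[3], 5), "insufficient history")
})

test_that("scaler standardizes, freezes, and inverts", {
  set.seed(9)
  x <- matrix(rnorm(600, mean = 5, sd = 3), 100, 6)
  sc <- fit_scaler(x)
  z <- apply_scaler(sc, x)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  expect_equal(invert_scaler(sc, z), x)
  # constant columns get sd 1 with a warning, transform stays finite
  x2 <- cbind(x, 7)
  expect_warning(sc2 <- fit_scaler(x2), "constant")
  expect_true(all(is.finite(apply_scaler(sc2, x2))))
})
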