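make_stack <- function(fnr_by_date, start = "2024-01-01") {
  # fnr_by_date: vector of daily values replicated over a 2 x 2 grid
  g <- grid_spec(0, 0.5, 0, 0.5, 0.25, 0.25)
  dates <- seq(as.Date(start), by = "day", length.out = length(fnr_by_date))
  a <- array(rep(fnr_by_date, each = 4), c(2, 2, length(fnr_by_date)))
  risk_map_stack(g, dates, a)
}

test_that("period and seasonal averages weight days correctly", {
  st <- make_stack(c(0.2, 0.4))
  expect_equal(unique(as.vector(period_average(st))), 0.3)
  cst <- make_stack(rep(0.5, 366))  # 2024 is a leap year
  expect_equal(unique(as.vector(seasonal_average(cst, "JJA", 2024))), 0.5)
  # month-constant year: seasonal mean is the day-count-weighted mean
  dates <- seq(as.Date("2023-01-01"), as.Date("2023-12-31"), by = "day")
  mo <- as.integer(format(dates, "%m"))
  vals <- mo / 20
  st2 <- make_stack(vals, "2023-01-01")
  for (season in c("MAM", "JJA", "SON")) {
    months <- habnet:::season_months(season)
    want <- sum((months / 20) * tabulate(mo)[months]) / sum(tabulate(mo)[months])
    expect_equal(unique(as.vector(seasonal_average(st2, season, 2023))), want)
  }
  # missing days are skipped in the mean
  a <- st$fnr; a[1, 1, 1] <- NA
  st3 <- risk_map_stack(st$grid, st$dates, a)
  expect_equal(period_average(st3)[1, 1], 0.4)
})

test_that("winter composes December with the following January/February", {
  dates <- seq(as.Date("2023-01-01"), as.Date("2024-12-31"), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  vals <- ifelse(yr == 2023 & mo == 12, 0.9,
                 ifelse(yr == 2024 & mo %in% 1:2, 0.3, 0.1))
  st <- make_stack(vals, "2023-01-01")
  got <- unique(as.vector(seasonal_average(st, "DJF", 2024)))
  want <- (31 * 0.9 + (31 + 29) * 0.3) / (31 + 31 + 29)
  expect_equal(got, want)
})

test_that("transition maps difference successive seasons and antisymmetrize", {
  dates <- seq(as.Date("2023-01-01"), as.Date("2023-12-31"), by = "day")
  mo <- as.integer(format(dates, "%m"))
  vals <- ifelse(mo %in% 3:5, 0.2, ifelse(mo %in% 6:8, 0.6, 0.1))
  st <- make_stack(vals, "2023-01-01")
  tr <- transition_difference(st, "MAM", "JJA", 2023)
  expect_equal(unique(as.vector(tr)), 0.4)
  expect_equal(transition_difference(st, "JJA", "MAM", 2023), -tr)
  expect_equal(unique(as.vector(transition_difference(st, "MAM", "MAM", 2023))), 0)
  # historical change in transition strength: identical stacks cancel
  tc <- transition_change(st, st, "MAM", "JJA", 2023, 2023)
  expect_equal(unique(as.vector(tc)), 0)
})

test_that("historical difference subtracts period averages", {
  recent <- make_stack(rep(0.6, 10))
  baseline <- make_stack(rep(0.5, 10), start = "1980-01-01")
  expect_equal(unique(as.vector(historical_difference(recent, baseline))),
               0.1, tolerance = 1e-12)
  expect_equal(unique(as.vector(historical_difference(recent, recent))), 0)
})

test_that("season diameter handles boxcars, constants, and wrap-around", {
  box <- rep(0, 365); box[100:199] <- 0.8
  d <- season_diameter(box)
  expect_equal(as.integer(d), 95)          # ceil(0.95 * 100 days of mass)
  expect_equal(attr(d, "start"), 100)      # earliest-start tie-break
  expect_equal(as.integer(season_diameter(rep(0.31, 365))), 347)  # ceil(0.95*365)
  # boxcar spanning the year boundary: window wraps, d stays small
  wrap <- rep(0, 365); wrap[c(349:365, 1:15)] <- 0.5  # Dec 15 .. Jan 15
  dw <- season_diameter(wrap)
  expect_equal(as.integer(dw), ceiling(0.95 * 32))
  expect_gte(attr(dw, "start"), 349)
  # degenerate all-zero series
  expect_true(is.na(season_diameter(rep(0, 365))))
  expect_error(season_diameter(c(-1, rep(0, 364))), "nonnegative")
})

test_that("season diameter equals the exhaustive circular-window oracle", {
  set.seed(41)
  for (i in 1:200) {
    kind <- i %% 4
    x <- switch(kind + 1,
      pmax(0, rnorm(365, 0.2, 0.2)),                             # noisy
      { z <- rep(0, 365); z[sample(365, 1) + 0:sample(20:120, 1)] <- runif(1); z[1:365] },
      { z <- runif(365) * 0.05; s <- sample(365, 1)
        z[(s + 0:59) %% 365 + 1] <- runif(60, 0.5, 1); z },      # wrap block
      rep(runif(1, 0.1, 0.9), 365))                              # constant
    x <- x[1:365]
    if (sum(x) == 0) next
    got <- season_diameter(x)
    want <- oracle_season_diameter(x)
    expect_equal(as.integer(got), as.integer(want))
    expect_equal(attr(got, "start"), attr(want, "start"))
  }
})

test_that("diameter shrinks with mass and ignores scale", {
  set.seed(42)
  x <- pmax(0, rnorm(365, 0.3, 0.25))
  d95 <- as.integer(season_diameter(x, 0.95))
  d50 <- as.integer(season_diameter(x, 0.50))
  d05 <- as.integer(season_diameter(x, 0.05))
  expect_true(d05 <= d50 && d50 <= d95)
  # unique-maximum series: d -> 1 as mass -> 0
  spike <- rep(0.001, 365); spike[200] <- 5
  expect_equal(as.integer(season_diameter(spike, 1e-4)), 1)
  # positive scaling changes neither diameter nor midpoint
  expect_identical(season_diameter(x), season_diameter(x * 7.3))
  expect_identical(season_midpoint(x), season_midpoint(x * 7.3))
})

test_that("season midpoint splits the cumulative mass", {
  box <- rep(0, 365); box[100:199] <- 0.8
  expect_true(season_midpoint(box) %in% c(149, 150))
  spike <- rep(0, 365); spike[237] <- 1
  expect_equal(season_midpoint(spike), 237)
  wrap <- rep(0, 365); wrap[c(349:365, 1:15)] <- 0.5
  mid <- season_midpoint(wrap)
  expect_lte(circular_doy_distance(mid, 1), 3)
})

test_that("annual series folds Feb 29 into day 59", {
  dates <- seq(as.Date("2024-01-01"), as.Date("2024-12-31"), by = "day")
  vals <- seq_along(dates) / 366
  st <- make_stack(vals, "2024-01-01")
  a <- annual_series(st, 2024)
  expect_equal(dim(a)[3], 365)
  expect_equal(a[1, 1, 59], (59 / 366 + 60 / 366) / 2)  # Feb 28 + Feb 29 averaged
  expect_equal(a[1, 1, 58], 58 / 366)
  expect_equal(a[1, 1, 365], 366 / 366)
  # non-leap years map one-to-one
  dates23 <- seq(as.Date("2023-01-01"), as.Date("2023-12-31"), by = "day")
  st23 <- make_stack(seq_along(dates23) / 365, "2023-01-01")
  expect_equal(annual_series(st23, 2023)[1, 1, ], seq_len(365) / 365)
})

test_that("exclusion mask drops near-New-Year midpoints and clips percentiles", {
  expect_equal(circular_doy_distance(360, 1), 6)
  expect_equal(circular_doy_distance(180, 1), 179)
  expect_equal(circular_doy_distance(11, 1), 10)
  prof <- structure(list(
    diameter = matrix(c(20, 40, 300, NA), 2, 2),
    seasonality = 1 / matrix(c(20, 40, 300, NA), 2, 2),
    midpoint = matrix(c(360, 180, 5, NA), 2, 2),
    total_mass = matrix(1, 2, 2), year = 2024, mass = 0.95,
    grid = grid_spec(0, 0.5, 0, 0.5, 0.25, 0.25)), class = "season_profile")
  em <- exclusion_mask(prof)
  expect_identical(as.vector(em$exclude), c(TRUE, FALSE, TRUE, TRUE))
  # type-7 order statistics on 1..100: (2.98, 98.02)
  prof2 <- prof
  prof2$seasonality <- matrix(1:100, 10, 10)
  prof2$midpoint <- matrix(180, 10, 10)
  prof2$diameter <- matrix(2, 10, 10)
  em2 <- exclusion_mask(prof2)
  expect_equal(em2$clip_range, c(2.98, 98.02))
})

test_that("season profiles recover a planted boxcar season from a stack", {
  n <- 365
  vals <- rep(0, n); vals[150:229] <- 0.6          # 80-day season
  st <- make_stack(vals, "2023-01-01")
  prof <- season_profile(st, 2023)
  expect_true(all(prof$diameter == ceiling(0.95 * 80)))
  expect_true(all(abs(prof$midpoint - 189) <= 2))
  expect_equal(unique(as.vector(prof$seasonality)),
               1 / ceiling(0.95 * 80))
  expect_true(all(abs(prof$total_mass - 80 * 0.6) < 1e-9))
})
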