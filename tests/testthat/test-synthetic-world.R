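test_that("climate law: gradient, seasonality, antiphase, determinism", {
  cfg <- world_config(n_lat = 12, n_lon = 16, years = 1, seed = 9)
  w <- generate_climate(cfg)
  expect_s3_class(w$cube, "climate_cube")
  expect_equal(length(w$cube$dates), 365)
  # annual-mean temperature decreases from equator to poles
  ann <- apply(w$cube$vars$tmean, 1, mean)
  lat <- grid_lats(w$cube$grid)
  expect_gt(ann[which.min(abs(lat))], ann[1] + 10)
  expect_gt(ann[which.min(abs(lat))], ann[12] + 10)
  # zero noise + zero amplitude: temporally constant cube
  cfg0 <- world_config(n_lat = 6, n_lon = 8, years = 1, seed = 9,
                       noise_sd = 0, seasonal_amp = 0, precip_noise_sd = 0,
                       wind_noise_sd = 0)
  w0 <- generate_climate(cfg0)
  expect_equal(max(abs(sweep(w0$cube$vars$tmean, c(1, 2),
                             w0$cube$vars$tmean[, , 1]))), 0,
               tolerance = 1e-9)
  # hemispheric antiphase: seasonal peaks ~182 days apart at +/-60 deg
  cfgA <- world_config(n_lat = 12, n_lon = 16, years = 1, seed = 9,
                       noise_sd = 0)
  wA <- generate_climate(cfgA)
  latA <- grid_lats(wA$cube$grid)
  north <- which.min(abs(latA - 60)); south <- which.min(abs(latA + 60))
  pk_n <- which.max(wA$cube$vars$tmean[north, 1, ])
  pk_s <- which.max(wA$cube$vars$tmean[south, 1, ])
  expect_lte(abs(abs(pk_n - pk_s) - 182.5), 1.5)
  # same seed, same cube
  w2 <- generate_climate(cfg)
  expect_identical(w2$cube$vars$tmean, w$cube$vars$tmean)
})

test_that("habitability law peaks at the thermal optimum", {
  cfg <- world_config(n_lat = 8, n_lon = 10, years = 1, seed = 4,
                      beta_p = 0, noise_sd = 0)
  w <- generate_climate(cfg)
  h <- habitability_field(w$cube, cfg)
  expect_true(all(is.na(h[, , 1:29])))
  t30 <- habnet:::trailing_mean(w$cube$vars$tmean, 30)
  # at the optimum the logistic hits plogis(beta0); further from the
  # optimum habitability only decreases
  dev <- abs(t30[, , 30:365] - cfg$t_opt)
  hh <- h[, , 30:365]
  expect_equal(max(hh, na.rm = TRUE),
               plogis(cfg$beta0 + cfg$beta_t * min(dev)^2))
  o <- order(dev)
  expect_true(all(diff(hh[o]) <= 1e-12))
  # scalar accessor agrees with the field
  i <- 40
  expect_equal(true_habitability(5, w$cube$dates[i], w$cube, cfg),
               h[, , i][5])
})

test_that("observation sampling follows effort and habitability", {
  cfg <- world_config(n_lat = 10, n_lon = 20, years = 1, seed = 2,
                      effort = 0.05)
  cm <- generate_climate(cfg)
  obs <- sample_observations(cfg, cm$cube, cm$mask)
  expect_gt(nrow(obs), 30)
  # all presences on land, inside the window, snapped cells consistent
  landv <- which(as.vector(cm$mask$is_land))
  expect_true(all(obs$cell %in% landv))
  expect_true(all(snap_to_cell(obs$lat, obs$lon, cm$cube$grid) == obs$cell))
  # zero effort -> empty table
  cfg0 <- cfg; cfg0$effort <- 0
  expect_equal(nrow(sample_observations(cfg0, cm$cube, cm$mask)), 0)
  # doubling effort roughly doubles the expected count (Monte Carlo)
  counts <- vapply(1:25, function(s) {
    c1 <- cfg; c1$seed <- 100 + s
    c2 <- cfg; c2$seed <- 100 + s; c2$effort <- 0.1
    c(nrow(sample_observations(c1, cm$cube, cm$mask)),
      nrow(sample_observations(c2, cm$cube, cm$mask)))
  }, numeric(2))
  ratio <- mean(counts[2, ]) / mean(counts[1, ])
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
})

test_that("population grid has hotspots and configured totals", {
  cfg <- world_config(n_lat = 10, n_lon = 20, years = 1)
  pop <- generate_population(cfg)
  expect_true(all(unlist(pop$counts) >= 0))
  expect_equal(sum(pop$counts[["1990"]]), cfg$pop_totals[1])
  expect_equal(sum(pop$counts[["2020"]]), cfg$pop_totals[2])
  # the density surface is peaked, not flat
  expect_gt(max(pop$counts[["1990"]]), 5 * median(pop$counts[["1990"]]))
})

test_that("seasonality recovery: a planted boxcar season is measured back", {
  # habitability confined to a known-length summer window at one latitude
  # band; the measured season diameter must match ceil(0.95 * L) within
  # a few days of discretization
  L <- 90
  vals <- rep(0.001, 365); vals[121:(120 + L)] <- 0.9
  g <- grid_spec(30, 35, 0, 5, 2.5, 2.5)
  dates <- seq(as.Date("2023-01-01"), by = "day", length.out = 365)
  st <- risk_map_stack(g, dates, array(rep(vals, each = 4), c(2, 2, 365)))
  prof <- season_profile(st, 2023)
  expect_true(all(abs(prof$diameter - ceiling(0.95 * L)) <= 3))
})
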