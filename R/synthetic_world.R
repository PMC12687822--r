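# Synthetic planet generator: climate cube, land mask, population, and
# presence observations drawn from a known habitability law. Gives every
# pipeline stage -- feature derivation, sampling, training, calibration,
# seasonality, burden -- a fully offline, ground-truthed test bed.
#
# The climate law is deliberately structural rather than realistic: an
# equator-to-pole mean-temperature gradient, a hemisphere-antiphase
# seasonal cycle, a wet-season precipitation cycle, and iid daily noise.
# Habitability is a logistic law on the 30-day trailing means of
# temperature (quadratic falloff around an optimum) and precipitation, so
# parameter recovery can be scored against a closed form.

#' Synthetic world configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 40 x 80 global grid, two simulated years, and an observation
#' effort tuned to yield roughly 500 presences in the final year.
#'
#' @param n_lat,n_lon Grid size (default 40 x 80; at least 4 x 4).
#' @param years Simulated years (default 2; the first year provides climate
#'   history only).
#' @param start_year First simulated calendar year.
#' @param seed Integer RNG seed for all stochastic steps.
#' @param base_temp Equatorial annual-mean temperature, deg C.
#' @param lat_gradient Equator-to-pole mean-temperature drop, deg C.
#' @param seasonal_amp Seasonal temperature amplitude, deg C
#'   (hemisphere-antiphase).
#' @param seasonal_phase Day-of-year phase of the seasonal cycle.
#' @param diurnal_range Daily max - min temperature, deg C.
#' @param dew_depression Mean dew-point depression, deg C.
#' @param noise_sd Daily temperature noise sd, deg C.
#' @param precip_base Mean hourly precipitation, mm/hr.
#' @param precip_amp Relative wet-season amplitude in `[0, 1]`.
#' @param precip_phase Day-of-year phase of the wet season.
#' @param precip_noise_sd Hourly precipitation noise sd, mm/hr.
#' @param wind_mean Mean wind speed scale, m/s.
#' @param wind_noise_sd Wind component noise sd, m/s.
#' @param t_opt Optimal 30-day mean temperature for the species, deg C.
#' @param beta0 Logistic intercept (habitability at the optimum when
#'   precipitation sits at `p_ref`).
#' @param beta_t Coefficient on `(T30 - t_opt)^2` (negative: quadratic
#'   falloff), per (deg C)^2.
#' @param beta_p Coefficient on `(P30 - p_ref)`, per mm/day.
#' @param p_ref Reference 30-day mean daily precipitation, mm/day.
#' @param trailing_days Trailing-mean window of the habitability law.
#' @param effort Observation effort: scalar or `[n_lat, n_lon]` matrix;
#'   P(record at cell-day) = `min(1, effort * habitability)`.
#' @param continents List of lat/lon boxes (each
#'   `list(lat = c(..), lon = c(..))`) defining land.
#' @param pop_census_years Two or more census years for the population
#'   grid.
#' @param pop_totals Total persons at each census year.
#' @return A `world_config` object.
#' @export
world_config <- function(n_lat = 40L, n_lon = 80L, years = 2L,
                         start_year = 2023L, seed = 1L,
                         base_temp = 28, lat_gradient = 45,
                         seasonal_amp = 10, seasonal_phase = 80,
                         diurnal_range = 8, dew_depression = 4,
                         noise_sd = 1.5,
                         precip_base = 0.12, precip_amp = 0.8,
                         precip_phase = 80, precip_noise_sd = 0.04,
                         wind_mean = 4, wind_noise_sd = 1.5,
                         t_opt = 26, beta0 = 1.0, beta_t = -0.08,
                         beta_p = 0.15, p_ref = 3, trailing_days = 30L,
                         effort = 0.007,
                         continents = list(
                           list(lat = c(-60, 75), lon = c(-150, -30)),
                           list(lat = c(-45, 70), lon = c(10, 140))),
                         pop_census_years = c(1990L, 2020L),
                         pop_totals = c(5e8, 8e8)) {
  stopifnot(n_lat >= 4, n_lon >= 4, years >= 1,
            seasonal_amp >= 0, noise_sd >= 0, precip_noise_sd >= 0,
            all(effort >= 0))
  structure(as.list(environment()), class = "world_config")
}

world_grid <- function(config) {
  grid_spec(-90, 90, -180, 180,
            180 / config$n_lat, 360 / config$n_lon)
}

world_dates <- function(config) {
  seq(as.Date(sprintf("%d-01-01", config$start_year)),
      as.Date(sprintf("%d-12-31", config$start_year + config$years - 1L)),
      by = "day")
}

#' Generate the synthetic climate cube and land mask
#'
#' Mean temperature follows
#' `base - gradient * |lat| / 90 + amp * sin(2 pi (doy - phase) / 365) * s(lat) + noise`
#' with `s(lat) = +1` in the northern and `-1` in the southern hemisphere
#' (seasonal peaks 182-183 days apart); max/min temperatures sit half a
#' diurnal range either side of the mean; dew point is the mean minus a
#' noisy depression; precipitation and winds are analogous sinusoid + noise
#' laws. Land is the union of the configured continental boxes.
#'
#' @param config A [world_config()].
#' @return List with `cube` (a raw [climate_cube()]) and `mask`
#'   (a [land_mask()]).
#' @export
generate_climate <- function(config) {
  grid <- world_grid(config)
  dates <- world_dates(config)
  nd <- length(dates)
  lat <- grid_lats(grid)
  doy <- as.integer(format(dates, "%j"))
  hemi <- ifelse(lat >= 0, 1, -1)
  nl <- grid$n_lat; no <- grid$n_lon
  ncell <- nl * no

  base_lat <- config$base_temp - config$lat_gradient * abs(lat) / 90     # [nl]
  seas <- sin(2 * pi * (doy - config$seasonal_phase) / 365)              # [nd]
  # [nl, no, nd] deterministic part, then iid noise
  det <- outer(matrix(base_lat, nl, no), rep(1, nd)) +
    outer(matrix(hemi, nl, no) * config$seasonal_amp,
          rep(1, nd)) * rep(seas, each = ncell)
  with_seed(config$seed, {
    tmean <- det + stats::rnorm(length(det), 0, config$noise_sd)
    tmax <- tmean + config$diurnal_range / 2
    tmin <- tmean - config$diurnal_range / 2
    dewpoint <- tmean - pmax(0.5, config$dew_depression +
                               stats::rnorm(length(det), 0, 1))
    pseas <- sin(2 * pi * (doy - config$precip_phase) / 365)
    pdet <- config$precip_base *
      (1 + config$precip_amp * outer(matrix(hemi, nl, no), rep(1, nd)) *
         rep(pseas, each = ncell))
    precip <- pmax(0, pdet + stats::rnorm(length(det), 0, config$precip_noise_sd))
    uwind <- 0.7 * config$wind_mean + stats::rnorm(length(det), 0, config$wind_noise_sd)
    vwind <- 0.3 * config$wind_mean + stats::rnorm(length(det), 0, config$wind_noise_sd)
    dim(tmean) <- dim(tmax) <- dim(tmin) <- dim(dewpoint) <-
      dim(precip) <- dim(uwind) <- dim(vwind) <- c(nl, no, nd)
    cube <- climate_cube(grid, dates, list(
      tmean = tmean, tmax = tmax, tmin = tmin, dewpoint = dewpoint,
      precip_hourly = precip, uwind = uwind, vwind = vwind))
  })

  is_land <- matrix(FALSE, nl, no)
  lon <- grid_lons(grid)
  for (box in config$continents)
    is_land <- is_land | outer(lat >= box$lat[1] & lat <= box$lat[2],
                               lon >= box$lon[1] & lon <= box$lon[2], "&")
  list(cube = cube, mask = land_mask(grid, is_land))
}

# trailing mean over `w` days (inclusive of the current day) along dim 3;
# first w-1 days are NA
trailing_mean <- function(arr, w) {
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  cs <- t(apply(m, 1, cumsum))
  out <- matrix(NA_real_, nrow(m), d[3])
  out[, w] <- cs[, w] / w
  if (d[3] > w)
    out[, (w + 1):d[3]] <- (cs[, (w + 1):d[3], drop = FALSE] -
                              cs[, 1:(d[3] - w), drop = FALSE]) / w
  array(out, d)
}

#' Ground-truth habitability field
#'
#' Evaluates the configured logistic law
#' `logit(h) = beta0 + beta_t * (T30 - t_opt)^2 + beta_p * (P30 - p_ref)`
#' on the 30-day trailing means of mean temperature (deg C) and total
#' daily precipitation (mm/day). Deterministic given the climate.
#'
#' @param cube The raw [climate_cube()] from [generate_climate()].
#' @param config The matching [world_config()].
#' @return `[n_lat, n_lon, n_dates]` array of probabilities; the first
#'   `trailing_days - 1` days are `NA`.
#' @export
habitability_field <- function(cube, config) {
  t30 <- trailing_mean(cube$vars$tmean, config$trailing_days)
  p30 <- trailing_mean(daily_precip_total(pmax(cube$vars$precip_hourly, 0)),
                       config$trailing_days)
  stats::plogis(config$beta0 + config$beta_t * (t30 - config$t_opt)^2 +
                  config$beta_p * (p30 - config$p_ref))
}

#' Ground-truth habitability at one cell-date
#'
#' Scalar convenience wrapper around [habitability_field()].
#'
#' @param cell Integer cell id.
#' @param date Date.
#' @param cube,config As in [habitability_field()].
#' @export
true_habitability <- function(cell, date, cube, config) {
  i <- date_index(cube$dates, date)
  if (is.na(i)) stop("date outside the cube")
  h <- habitability_field(cube, config)
  h[cell + (i - 1) * n_cells(cube$grid)]
}

#' Sample presence observations from the habitability field
#'
#' A thinned point process: each land cell-day inside the window records a
#' presence with probability `min(1, effort(cell) * habitability)`.
#' Recorded coordinates are jittered uniformly within the cell.
#'
#' @param config A [world_config()].
#' @param cube The raw climate cube.
#' @param mask The [land_mask()].
#' @param window Length-2 `Date` vector; default: the final simulated year.
#' @param species Species label stored in the table.
#' @return An `observation_table` data frame (`species`, `date`, `lat`,
#'   `lon`, `label = 1`, `cell`).
#' @export
sample_observations <- function(config, cube, mask,
                                window = NULL, species = "Aedes synthetica") {
  grid <- cube$grid
  if (is.null(window)) {
    y_last <- config$start_year + config$years - 1L
    window <- as.Date(sprintf(c("%d-01-01", "%d-12-31"), y_last))
  }
  window <- as.Date(window)
  h <- habitability_field(cube, config)
  keep_t <- which(cube$dates >= window[1] & cube$dates <= window[2])
  eff <- config$effort
  if (is.matrix(eff)) stopifnot(all(dim(eff) == c(grid$n_lat, grid$n_lon)))
  effv <- if (is.matrix(eff)) as.vector(eff) else rep(eff, n_cells(grid))
  landv <- as.vector(mask$is_land)
  recs <- with_seed(config$seed + 7L, {
    out <- vector("list", length(keep_t))
    for (k in seq_along(keep_t)) {
      t <- keep_t[k]
      p <- effv * h[, , t][seq_len(n_cells(grid))]
      p[!landv | is.na(p)] <- 0
      p <- pmin(p, 1)
      hit <- which(stats::runif(length(p)) < p)
      if (length(hit))
        out[[k]] <- data.frame(cell = hit, date = cube$dates[t])
    }
    rec <- do.call(rbind, out)
    if (!is.null(rec) && nrow(rec)) {
      ctr <- cell_center(grid, rec$cell)
      rec$lat <- ctr[, "lat"] +
        stats::runif(nrow(rec), -0.5, 0.5) * grid$cell_size_lat
      rec$lon <- ctr[, "lon"] +
        stats::runif(nrow(rec), -0.5, 0.5) * grid$cell_size_lon
    }
    rec
  })
  if (is.null(recs) || nrow(recs) == 0) {
    out <- data.frame(species = character(0), date = as.Date(character(0)),
                      lat = numeric(0), lon = numeric(0),
                      label = integer(0), cell = integer(0))
  } else {
    out <- data.frame(species = species, date = recs$date,
                      lat = pmin(pmax(recs$lat, -90), 90),
                      lon = normalize_lon(recs$lon),
                      label = 1L, cell = recs$cell,
                      stringsAsFactors = FALSE)
  }
  attr(out, "world_config") <- config
  class(out) <- c("observation_table", "data.frame")
  out
}

#' Generate the synthetic population grid
#'
#' A smooth base density plus Gaussian hotspots (centered on the
#' continents), scaled so each census year hits its configured total.
#'
#' @param config A [world_config()].
#' @return A [population_grid()].
#' @export
generate_population <- function(config) {
  grid <- world_grid(config)
  lat <- grid_lats(grid); lon <- grid_lons(grid)
  hotspots <- lapply(config$continents, function(box)
    c(lat = mean(box$lat) / 2, lon = mean(box$lon)))
  dens <- matrix(1, grid$n_lat, grid$n_lon)
  for (hs in hotspots) {
    d2 <- outer((lat - hs["lat"])^2, (lon - hs["lon"])^2, "+")
    dens <- dens + 60 * exp(-d2 / (2 * 25^2))
  }
  counts <- lapply(config$pop_totals, function(tot) dens / sum(dens) * tot)
  population_grid(grid, config$pop_census_years, counts)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: climate + mask + derived covariates + habitability
#' field + presence observations + population.
#'
#' @param config A [world_config()].
#' @return List with `config`, `cube`, `mask`, `derived`, `habitability`,
#'   `observations`, `population`.
#' @export
generate_world <- function(config = world_config()) {
  cm <- generate_climate(config)
  list(config = config, cube = cm$cube, mask = cm$mask,
       derived = derive_all(cm$cube),
       habitability = habitability_field(cm$cube, config),
       observations = sample_observations(config, cm$cube, cm$mask),
       population = generate_population(config))
}
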