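# Population-days at risk: FNR stacks x gridded population.

#' Linearly interpolate population to an arbitrary year
#'
#' Per-cell linear interpolation between the bracketing census years;
#' exact at census years.
#'
#' @param pop A [population_grid()].
#' @param year Target year, within the census range.
#' @return `[n_lat, n_lon]` matrix of persons per cell.
#' @export
interpolate_population <- function(pop, year) {
  ys <- pop$census_years
  if (year < ys[1] || year > ys[length(ys)])
    stop("year ", year, " outside census range [", ys[1], ", ",
         ys[length(ys)], "]")
  if (year %in% ys) return(pop$counts[[as.character(year)]])
  i <- findInterval(year, ys)
  y0 <- ys[i]; y1 <- ys[i + 1]
  w <- (year - y0) / (y1 - y0)
  (1 - w) * pop$counts[[as.character(y0)]] + w * pop$counts[[as.character(y1)]]
}

#' Interpolate a daily FNR stack between modeled years
#'
#' For a target year without explicit predictions, pairs days of year
#' across the bracketing modeled years (Feb 29 folded as in
#' [annual_series()]) and interpolates linearly per cell per day; results
#' are clamped to `[0, 1]`.
#'
#' @param stacks Named list (by year, as character) of [risk_map_stack()]s.
#' @param target_year Integer year.
#' @return `[n_lat, n_lon, 365]` array for the target year.
#' @export
interpolate_fnr_year <- function(stacks, target_year) {
  years <- sort(as.integer(names(stacks)))
  if (target_year < years[1] || target_year > years[length(years)])
    stop("target year outside modeled range")
  series_of <- function(y) annual_series(stacks[[as.character(y)]], y)
  if (target_year %in% years) return(series_of(target_year))
  i <- findInterval(target_year, years)
  y0 <- years[i]; y1 <- years[i + 1]
  w <- (target_year - y0) / (y1 - y0)
  out <- (1 - w) * series_of(y0) + w * series_of(y1)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Person-days at risk
#'
#' Sums, over the region's cells and all days, the population of each cell
#' whose FNR meets the threshold: `sum_{cell, day} pop(cell) *
#' 1[FNR(cell, day) >= threshold]`. Missing FNR values contribute nothing.
#'
#' @param fnr `[n_lat, n_lon, n_days]` FNR array (or a [risk_map_stack()]).
#' @param pop_raster `[n_lat, n_lon]` matrix of persons per cell.
#' @param threshold Inclusive FNR threshold (default 0.5, "high risk").
#' @param region_mask Optional logical `[n_lat, n_lon]` matrix restricting
#'   the sum.
#' @return Person-days (scalar).
#' @export
person_days_at_risk <- function(fnr, pop_raster, threshold = 0.5,
                                region_mask = NULL) {
  if (inherits(fnr, "risk_map_stack")) fnr <- fnr$fnr
  d <- dim(fnr)
  stopifnot(length(d) == 3, all(dim(pop_raster) == d[1:2]))
  pop <- pop_raster
  if (!is.null(region_mask)) {
    stopifnot(all(dim(region_mask) == d[1:2]))
    pop <- pop * (region_mask %in% TRUE)
    dim(pop) <- d[1:2]
  }
  at_risk <- fnr >= threshold
  at_risk[is.na(at_risk)] <- FALSE
  days_at_risk <- rowSums(matrix(at_risk, d[1] * d[2], d[3]))
  sum(as.vector(pop) * days_at_risk, na.rm = TRUE)
}

#' Build a region mask from a lat/lon box
#'
#' @param grid A [grid_spec()].
#' @param lat_range,lon_range Length-2 numeric vectors (degrees).
#' @return Logical `[n_lat, n_lon]` matrix (`TRUE` = cell center inside).
#' @export
region_box_mask <- function(grid, lat_range, lon_range) {
  lat <- grid_lats(grid); lon <- grid_lons(grid)
  outer(lat >= lat_range[1] & lat <= lat_range[2],
        lon >= lon_range[1] & lon <= lon_range[2], "&")
}

#' Yearly burden series
#'
#' Person-days at risk per year, combining interpolated FNR (between
#' modeled years) with interpolated population (between census years).
#'
#' @param stacks Named list (by year) of [risk_map_stack()]s.
#' @param pop A [population_grid()] on the same grid.
#' @param years Integer years to evaluate.
#' @param threshold FNR threshold (default 0.5).
#' @param region_mask Optional logical matrix.
#' @param region,species Labels carried in the result.
#' @return A `burden_series` data frame with `year` and `person_days`.
#' @export
burden_series <- function(stacks, pop, years, threshold = 0.5,
                          region_mask = NULL, region = "global",
                          species = "") {
  pd <- vapply(years, function(y) {
    person_days_at_risk(interpolate_fnr_year(stacks, y),
                        interpolate_population(pop, y),
                        threshold, region_mask)
  }, numeric(1))
  structure(data.frame(year = years, person_days = pd),
            class = c("burden_series", "data.frame"),
            region = region, species = species, threshold = threshold)
}

#' Linear trend with prediction interval
#'
#' Ordinary least squares of person-days on year, with the standard
#' t-based prediction interval at the requested level.
#'
#' @param series A `burden_series` (or data frame with `year`,
#'   `person_days`).
#' @param level Prediction-interval level (default 0.90).
#' @return A `trend_fit`: list with `slope`, `intercept`, and a data frame
#'   `interval` (`year`, `fit`, `lwr`, `upr`).
#' @export
fit_trend <- function(series, level = 0.90) {
  stopifnot(nrow(series) >= 3)
  fit <- stats::lm(person_days ~ year, data = series)
  pr <- stats::predict(fit, newdata = series, interval = "prediction",
                       level = level)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 level = level,
                 interval = data.frame(year = series$year,
                                       fit = pr[, "fit"], lwr = pr[, "lwr"],
                                       upr = pr[, "upr"]),
                 lm = fit),
            class = "trend_fit")
}
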