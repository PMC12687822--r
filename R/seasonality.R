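# Temporal analytics on daily FNR stacks: period/seasonal averages,
# transition maps, circular season diameter & midpoint, historical change,
# and the visualization exclusion mask.
#
# The "mosquito season" of a location is the shortest circular window of
# days (wrapping December into January) holding 95% of the year's
# cumulative FNR mass; its length d is the season diameter and seasonality
# is reported as 1/d. Working on the circle removes the constraint that a
# season must begin and end in the same calendar year.

#' Average an FNR stack over a date range
#'
#' @param stack A [risk_map_stack()].
#' @param date_range Length-2 vector (min, max); default: whole stack.
#' @return `[n_lat, n_lon]` matrix of per-cell means over available days
#'   (cells missing every day give `NA`).
#' @export
period_average <- function(stack, date_range = range(stack$dates)) {
  date_range <- as.Date(date_range)
  keep <- stack$dates >= date_range[1] & stack$dates <= date_range[2]
  if (!any(keep)) stop("no stack dates inside the requested range")
  apply(stack$fnr[, , keep, drop = FALSE], c(1, 2),
        function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

season_months <- function(season) {
  switch(season,
         MAM = 3:5, JJA = 6:8, SON = 9:11, DJF = c(12, 1, 2),
         stop("season must be one of MAM, JJA, SON, DJF"))
}

#' Seasonal average of an FNR stack
#'
#' Means over all days of the named season in the requested years.
#' Winter (DJF) of year `y` is composed of December of `y - 1` plus
#' January and February of `y`.
#'
#' @param stack A [risk_map_stack()].
#' @param season `"MAM"`, `"JJA"`, `"SON"`, or `"DJF"`.
#' @param years Integer years.
#' @return `[n_lat, n_lon]` matrix.
#' @export
seasonal_average <- function(stack, season, years) {
  mo <- as.integer(format(stack$dates, "%m"))
  yr <- as.integer(format(stack$dates, "%Y"))
  months <- season_months(season)
  if (identical(season, "DJF")) {
    # assign December to the following winter's year
    season_year <- ifelse(mo == 12L, yr + 1L, yr)
  } else {
    season_year <- yr
  }
  keep <- mo %in% months & season_year %in% years
  if (!any(keep)) stop("no stack dates in season ", season,
                       " for the requested years")
  apply(stack$fnr[, , keep, drop = FALSE], c(1, 2),
        function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Difference between successive seasonal averages
#'
#' `seasonal_average(season_to) - seasonal_average(season_from)`: the
#' intensity of the seasonal transition.
#'
#' @inheritParams seasonal_average
#' @param season_from,season_to Season codes.
#' @export
transition_difference <- function(stack, season_from, season_to, years) {
  seasonal_average(stack, season_to, years) -
    seasonal_average(stack, season_from, years)
}

#' Change in mean FNR between two periods
#'
#' `period_average(recent) - period_average(baseline)`; positive values
#' mark increased risk relative to the baseline period.
#'
#' @param stack_recent,stack_baseline [risk_map_stack()]s.
#' @export
historical_difference <- function(stack_recent, stack_baseline) {
  period_average(stack_recent) - period_average(stack_baseline)
}

#' Historical change in the strength of a seasonal transition
#'
#' `|transition| recent - |transition| baseline`: negative values reflect
#' temporal homogenization (the seasonal contrast has weakened relative to
#' the baseline), positive values temporal diversification.
#'
#' @inheritParams historical_difference
#' @param season_from,season_to Season codes.
#' @param years_recent,years_baseline Years evaluated in each stack.
#' @export
transition_change <- function(stack_recent, stack_baseline,
                              season_from, season_to,
                              years_recent, years_baseline) {
  abs(transition_difference(stack_recent, season_from, season_to, years_recent)) -
    abs(transition_difference(stack_baseline, season_from, season_to, years_baseline))
}

#' Fold one year of a stack into a 365-day series array
#'
#' Feb 29 is averaged into the day-of-year 59 bucket so every series has
#' length exactly 365.
#'
#' @param stack A [risk_map_stack()].
#' @param year Calendar year to extract.
#' @return `[n_lat, n_lon, 365]` array.
#' @export
annual_series <- function(stack, year) {
  yr <- as.integer(format(stack$dates, "%Y"))
  keep <- which(yr == year)
  if (!length(keep)) stop("stack has no dates in year ", year)
  doy <- as.integer(format(stack$dates[keep], "%j"))
  leap <- length(keep) && any(doy == 366)
  out <- array(NA_real_, c(stack$grid$n_lat, stack$grid$n_lon, 365))
  if (leap) {
    # days 60..366 of a leap year are calendar days 59..365; Feb 29
    # (doy 60) is averaged with Feb 28 into bucket 59
    bucket <- ifelse(doy >= 60, doy - 1L, doy)
    for (b in unique(bucket)) {
      sel <- keep[bucket == b]
      out[, , b] <- apply(stack$fnr[, , sel, drop = FALSE], c(1, 2), mean)
    }
  } else {
    out[, , doy] <- stack$fnr[, , keep]
  }
  out
}

# circular minimal-window search: smallest L (ties: earliest start) with
# window sum >= mass * total; two-pointer sweep over the doubled series
min_circular_window <- function(x, mass) {
  n <- length(x)
  total <- sum(x)
  if (!is.finite(total) || total <= 0) return(c(NA_integer_, NA_integer_))
  target <- mass * total - 1e-9 * total
  xx <- c(x, x)
  best_d <- n + 1L; best_s <- 1L
  j <- 0L; acc <- 0
  for (s in seq_len(n)) {
    if (j < s) { j <- s - 1L; acc <- 0 }
    while (j < s + n - 1L && acc < target) {
      j <- j + 1L
      acc <- acc + xx[j]
    }
    if (acc >= target) {
      d <- j - s + 1L
      if (d < best_d) { best_d <- d; best_s <- s }
    }
    acc <- acc - xx[s]
  }
  c(best_d, best_s)
}

#' Season diameter of a daily FNR series
#'
#' The length of the shortest circular window of days whose FNR sum reaches
#' `mass` (default 95%) of the series total. Ties are broken toward the
#' earliest starting day. An all-zero series is degenerate and returns `NA`.
#'
#' @param series Numeric vector of 365 daily FNR values (nonnegative).
#' @param mass Cumulative-mass fraction defining the season (default 0.95).
#' @return Integer diameter `d` in days (attribute `start` holds the
#'   window's first day-of-year), or `NA` for a degenerate series.
#' @examples
#' x <- rep(0, 365); x[100:199] <- 0.8
#' season_diameter(x)  # 95
#' @export
season_diameter <- function(series, mass = 0.95) {
  stopifnot(length(series) == 365, mass > 0, mass <= 1)
  if (any(series < 0, na.rm = TRUE)) stop("FNR series must be nonnegative")
  series[is.na(series)] <- 0
  ds <- min_circular_window(series, mass)
  if (is.na(ds[1])) return(NA_integer_)
  structure(ds[1], start = ds[2])
}

#' Season midpoint of a daily FNR series
#'
#' Within the (earliest-starting) season-diameter window, the first day at
#' which the cumulative FNR from the window start reaches half of the
#' series' total mass -- the day splitting the location's cumulative FNR
#' into (roughly) equal halves, robust to seasons spanning New Year.
#'
#' @inheritParams season_diameter
#' @return Calendar day-of-year (1..365), or `NA` for a degenerate series.
#' @export
season_midpoint <- function(series, mass = 0.95) {
  d <- season_diameter(series, mass)
  if (is.na(d)) return(NA_integer_)
  s <- attr(d, "start")
  series[is.na(series)] <- 0
  total <- sum(series)
  days <- ((s - 1L) + seq_len(d) - 1L) %% 365L + 1L
  cum <- cumsum(series[days])
  k <- which(cum >= total / 2 - 1e-12 * total)[1]
  days[k]
}

#' Per-cell season profiles for one year
#'
#' @param stack A [risk_map_stack()] covering `year`.
#' @param year Calendar year.
#' @param mass Season mass fraction (default 0.95).
#' @return A `season_profile`: list of `[n_lat, n_lon]` matrices
#'   `diameter` (days), `seasonality` (`1/d` per day), `midpoint`
#'   (day-of-year), `total_mass`; degenerate (zero-mass) cells are `NA`.
#' @export
season_profile <- function(stack, year, mass = 0.95) {
  a <- annual_series(stack, year)
  nl <- stack$grid$n_lat; no <- stack$grid$n_lon
  dia <- mid <- tot <- matrix(NA_real_, nl, no)
  for (i in seq_len(nl)) for (j in seq_len(no)) {
    x <- a[i, j, ]
    if (all(is.na(x))) next
    x[is.na(x)] <- 0
    tot[i, j] <- sum(x)
    d <- season_diameter(x, mass)
    if (!is.na(d)) {
      dia[i, j] <- as.integer(d)
      s <- attr(d, "start")
      days <- ((s - 1L) + seq_len(d) - 1L) %% 365L + 1L
      cum <- cumsum(x[days])
      k <- which(cum >= tot[i, j] / 2 - 1e-12 * tot[i, j])[1]
      mid[i, j] <- days[k]
    }
  }
  structure(list(diameter = dia, seasonality = 1 / dia, midpoint = mid,
                 total_mass = tot, year = year, mass = mass,
                 grid = stack$grid),
            class = "season_profile")
}

#' Circular day-of-year distance
#' @param a,b Days of year (1..365).
#' @return Shortest distance around the 365-day circle.
#' @export
circular_doy_distance <- function(a, b) {
  d <- abs(a - b) %% 365
  pmin(d, 365 - d)
}

#' Visualization exclusion mask for season profiles
#'
#' Masks cells whose season midpoint falls within `window` days of
#' January 1 (circularly) -- these are locations with negligible cumulative
#' FNR whose "season" is an artifact -- and returns the 2nd/98th percentile
#' clip range of the remaining seasonality values (type-7 quantiles). The
#' mask and range are aids for map rendering only; they feed no other
#' computation.
#'
#' @param profile A [season_profile()].
#' @param window Exclusion half-width in days (default 10).
#' @param probs Clip percentiles (default `c(0.02, 0.98)`).
#' @return List with `exclude` (logical matrix; `TRUE` = masked) and
#'   `clip_range` (length-2 numeric).
#' @export
exclusion_mask <- function(profile, window = 10, probs = c(0.02, 0.98)) {
  mid <- profile$midpoint
  excl <- !is.na(mid) & circular_doy_distance(mid, 1) <= window
  excl[is.na(mid)] <- TRUE
  vals <- profile$seasonality[!excl & !is.na(profile$seasonality)]
  rng <- if (length(vals)) stats::quantile(vals, probs, names = FALSE, type = 7)
         else c(NA_real_, NA_real_)
  list(exclude = excl, clip_range = rng)
}
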