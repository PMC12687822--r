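# Derived daily climate covariates and flattened feature sequences.

#' Relative humidity from dew point and air temperature
#'
#' August-Roche-Magnus form:
#' `RH = 100 * exp(17.625 * T_d / (243.04 + T_d)) / exp(17.625 * T_m / (243.04 + T_m))`.
#' The result is not clipped at 100: reanalysis fields occasionally imply
#' supersaturation (dew point above air temperature) and the downstream
#' normalization absorbs the scale.
#'
#' @param t_d Dew point temperature, deg C.
#' @param t_m Mean 2-m air temperature, deg C.
#' @return Relative humidity in percent. `relative_humidity(t, t)` is exactly
#'   100 for any valid `t`.
#' @examples
#' relative_humidity(15, 15)  # 100
#' relative_humidity(0, 20)   # ~26.2
#' @export
relative_humidity <- function(t_d, t_m) {
  if (any(t_d <= -243.04) || any(t_m <= -243.04))
    stop("temperatures must exceed -243.04 deg C (Magnus denominator)")
  100 * exp(17.625 * t_d / (243.04 + t_d)) / exp(17.625 * t_m / (243.04 + t_m))
}

#' Total daily precipitation from the average hourly rate
#' @param avg_hourly Average hourly precipitation, mm/hr; nonnegative.
#' @return Total daily precipitation in mm/day (`24 * avg_hourly`).
#' @export
daily_precip_total <- function(avg_hourly) {
  if (any(avg_hourly < 0, na.rm = TRUE)) stop("negative hourly precipitation")
  24 * avg_hourly
}

#' Wind speed magnitude from u/v components
#' @param u,v Wind components, m/s.
#' @return `sqrt(u^2 + v^2)`, m/s.
#' @export
wind_magnitude <- function(u, v) sqrt(u^2 + v^2)

#' Diurnal temperature range
#'
#' Negative ranges (small reanalysis artifacts where the reported minimum
#' exceeds the maximum) are clamped to zero with a warning.
#' @param t_max,t_min Daily max/min 2-m air temperature, deg C.
#' @return `t_max - t_min`, floored at 0.
#' @export
temperature_range <- function(t_max, t_min) {
  r <- t_max - t_min
  bad <- which(r < 0)
  if (length(bad)) {
    warning(length(bad), " negative temperature range value(s) clamped to 0")
    r[bad] <- 0
  }
  r
}

#' Compute the five derived daily covariates from a raw climate cube
#'
#' Produces `trange` (deg C), `tmean` (deg C; the ERA5 daily-mean 2-m
#' temperature is used as the central-temperature covariate), `rh` (%),
#' `ptot` (mm/day), and `wspd` (m/s) on the same grid and date index as the
#' input. Negative hourly-precipitation artifacts are clamped to zero; the
#' count of clamped values is attached as attribute `n_precip_clamped`.
#'
#' @param cube A raw [climate_cube()] with the seven input variables.
#' @return A `derived_cube` (see [climate_cube()]).
#' @export
derive_all <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  need <- c("tmean", "tmax", "tmin", "dewpoint", "precip_hourly", "uwind", "vwind")
  miss <- setdiff(need, names(cube$vars))
  if (length(miss)) stop("raw cube missing variables: ", paste(miss, collapse = ", "))
  ph <- cube$vars$precip_hourly
  n_clamped <- sum(ph < 0, na.rm = TRUE)
  if (n_clamped > 0) ph[ph < 0] <- 0
  tr <- cube$vars$tmax - cube$vars$tmin
  tr[tr < 0] <- 0
  out <- climate_cube(cube$grid, cube$dates, list(
    trange = tr,
    tmean = cube$vars$tmean,
    rh = relative_humidity(cube$vars$dewpoint, cube$vars$tmean),
    ptot = daily_precip_total(ph),
    wspd = wind_magnitude(cube$vars$uwind, cube$vars$vwind)
  ), class = "derived_cube")
  attr(out, "n_precip_clamped") <- n_clamped
  out
}

#' Canonical derived-variable order
#'
#' The fixed variable order used when flattening sequences; recorded in every
#' trained model so feature layouts are never silently incompatible.
#' @return `c("trange", "tmean", "rh", "ptot", "wspd")`
#' @export
derived_variables <- function() DERIVED_VARS

# column permutation mapping var-major (v1 d1..dL, v2 d1..dL, ...) to
# day-major (d1 v1..vV, d2 v1..vV, ...) layout
day_major_perm <- function(seq_len, n_vars) {
  as.vector(vapply(seq_len(seq_len),
                   function(d) (seq_len(n_vars) - 1L) * seq_len + d,
                   integer(n_vars)))
}

#' Assemble one flattened feature sequence
#'
#' Extracts the `seq_len` days strictly before `date` (the observation day
#' itself is excluded) for one grid cell and flattens them day-major, oldest
#' day first, with the variables of each day in [derived_variables()] order
#' (or `vars` if given).
#'
#' @param cube A `derived_cube` from [derive_all()].
#' @param cell Integer cell id.
#' @param date Target date; features cover `date - seq_len` .. `date - 1`.
#' @param seq_len Number of prior days (paper range 30-365).
#' @param vars Variable subset (default all five, in canonical order).
#' @return Numeric vector of length `seq_len * length(vars)`.
#' @export
assemble_sequence <- function(cube, cell, date, seq_len, vars = derived_variables()) {
  m <- assemble_features(cube, cell, date, seq_len, vars)
  drop(m)
}

#' Assemble flattened feature sequences for many (cell, date) rows
#'
#' Vectorized companion of [assemble_sequence()]; rows lacking `seq_len` days
#' of history raise an error naming the earliest missing date.
#'
#' @inheritParams assemble_sequence
#' @param cell,date Parallel vectors of cell ids and dates.
#' @return Matrix `[n_rows, seq_len * length(vars)]`.
#' @export
assemble_features <- function(cube, cell, date, seq_len, vars = derived_variables()) {
  stopifnot(inherits(cube, "derived_cube"))
  miss <- setdiff(vars, names(cube$vars))
  if (length(miss)) stop("cube lacks variables: ", paste(miss, collapse = ", "))
  date <- as.Date(date)
  n <- max(length(cell), length(date))
  cell <- rep_len(as.integer(cell), n); date <- rep_len(date, n)
  idx <- date_index(cube$dates, date)
  if (anyNA(idx)) stop("date(s) outside the cube date index: ",
                       format(date[which(is.na(idx))[1]]))
  if (any(idx <= seq_len)) {
    bad <- which(idx <= seq_len)[1]
    stop(sprintf("insufficient history for %s: need days back to %s but cube starts %s",
                 format(date[bad]), format(date[bad] - seq_len),
                 format(cube$dates[1])))
  }
  nc <- n_cells(cube$grid)
  L <- as.integer(seq_len)
  V <- length(vars)
  out <- matrix(NA_real_, n, L * V)
  # flat index into [cell, day] for each (row, lag) pair; oldest lag first
  day_off <- if (L == 1L) matrix(idx - 1L, n, 1L)
             else t(vapply(idx, function(i) (i - L):(i - 1), integer(L)))  # n x L
  flat <- matrix(cell, n, L) + (day_off - 1L) * nc                     # n x L
  for (v in seq_len(V)) {
    av <- cube$vars[[vars[v]]]
    dim(av) <- c(nc * length(cube$dates))
    out[, (v - 1L) * L + seq_len(L)] <- av[flat]
  }
  out[, day_major_perm(L, V), drop = FALSE]
}

#' Assemble the feature matrix for every grid cell at one date
#'
#' Used for map prediction: one row per cell id (1..n_cells), day-major
#' flattening as in [assemble_features()]. Cells with any missing climate
#' value in the window get `NA` rows.
#'
#' @inheritParams assemble_sequence
#' @return Matrix `[n_cells, seq_len * length(vars)]`.
#' @export
assemble_date_matrix <- function(cube, date, seq_len, vars = derived_variables()) {
  nc <- n_cells(cube$grid)
  assemble_features(cube, seq_len(nc), rep(as.Date(date), nc), seq_len, vars)
}

#' Fit / apply z-score normalization
#'
#' `fit_scaler` computes per-column means and standard deviations on the
#' training feature matrix only (leakage guard); columns with zero variance
#' get `sd = 1` with a warning. `apply_scaler` standardizes any matrix with
#' frozen statistics; `invert_scaler` undoes it.
#'
#' @param x Numeric feature matrix (rows = examples).
#' @return `fit_scaler`: a `scaler_stats` object with `mean` and `sd`
#'   vectors; the others: a transformed matrix.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  const <- which(!is.finite(s) | s <= 0)
  if (length(const)) {
    warning(length(const), " constant feature column(s); sd set to 1")
    s[const] <- 1
  }
  structure(list(mean = m, sd = s), class = "scaler_stats")
}

#' @rdname fit_scaler
#' @param scaler A `scaler_stats` object.
#' @export
apply_scaler <- function(scaler, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  stopifnot(ncol(x) == length(scaler$mean))
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  sweep(sweep(x, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}
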