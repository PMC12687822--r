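# Core containers: climate cubes, land masks, population grids, risk stacks.
# All rasters are [n_lat, n_lon] matrices (row = latitude south-to-north);
# stacks add a third, date, dimension.

RAW_VARS <- c("tmean", "tmax", "tmin", "dewpoint", "precip_hourly", "uwind", "vwind")
DERIVED_VARS <- c("trange", "tmean", "rh", "ptot", "wspd")

#' Daily multi-variable climate cube
#'
#' Bundles a [grid_spec()], a contiguous daily date index, and one
#' `[n_lat, n_lon, n_dates]` array per climate variable. Raw cubes carry the
#' seven input variables (`tmean`, `tmax`, `tmin`, `dewpoint` in deg C,
#' `precip_hourly` in mm/hr, `uwind`/`vwind` in m/s); derived cubes (see
#' [derive_all()]) carry `trange`, `tmean`, `rh`, `ptot`, `wspd`.
#'
#' @param grid A [grid_spec()].
#' @param dates A contiguous `Date` vector.
#' @param vars Named list of `[n_lat, n_lon, n_dates]` arrays.
#' @param class Extra S3 class prepended (`"climate_cube"` or
#'   `"derived_cube"`).
#' @return A `climate_cube` object.
#' @export
climate_cube <- function(grid, dates, vars, class = "climate_cube") {
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("empty date index")
  if (length(dates) > 1 && any(diff(dates) != 1)) {
    gaps <- dates[which(diff(dates) != 1)] + 1
    stop("date index has gaps; first missing date: ", format(gaps[1]))
  }
  stopifnot(is.list(vars), length(vars) > 0, !is.null(names(vars)))
  for (v in names(vars)) {
    d <- dim(vars[[v]])
    if (is.null(d) || length(d) != 3 ||
        d[1] != grid$n_lat || d[2] != grid$n_lon || d[3] != length(dates))
      stop(sprintf("variable '%s' has shape (%s); expected (%d, %d, %d)",
                   v, paste(d, collapse = ", "),
                   grid$n_lat, grid$n_lon, length(dates)))
  }
  structure(list(grid = grid, dates = dates, vars = vars),
            class = unique(c(class, "climate_cube")))
}

#' @export
print.climate_cube <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %d dates (%s .. %s), vars: %s\n",
              class(x)[1], x$grid$n_lat, x$grid$n_lon, length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              paste(names(x$vars), collapse = ", ")))
  invisible(x)
}

#' Land/sea mask on a grid
#' @param grid A [grid_spec()].
#' @param is_land Logical `[n_lat, n_lon]` matrix; must contain land.
#' @export
land_mask <- function(grid, is_land) {
  is_land <- matrix(as.logical(is_land), grid$n_lat, grid$n_lon)
  if (!any(is_land, na.rm = TRUE)) stop("land mask has no land cells")
  structure(list(grid = grid, is_land = is_land), class = "land_mask")
}

#' Gridded population at census years
#'
#' Population is stored as persons per cell (not density), so that
#' resampling can conserve total persons.
#'
#' @param grid A [grid_spec()].
#' @param census_years Integer vector (ascending, length >= 2).
#' @param counts Named list (by year) of `[n_lat, n_lon]` matrices of
#'   persons per cell; nonnegative.
#' @export
population_grid <- function(grid, census_years, counts) {
  census_years <- as.integer(census_years)
  if (length(census_years) < 2) stop("need at least two census years")
  if (is.unsorted(census_years, strictly = TRUE)) stop("census years must be strictly ascending")
  stopifnot(length(counts) == length(census_years))
  names(counts) <- as.character(census_years)
  for (y in names(counts)) {
    m <- counts[[y]]
    if (!all(dim(m) == c(grid$n_lat, grid$n_lon)))
      stop("population raster shape mismatch for year ", y)
    if (any(m < 0, na.rm = TRUE)) stop("negative population in year ", y)
  }
  structure(list(grid = grid, census_years = census_years, counts = counts),
            class = "population_grid")
}

#' Daily risk-map stack (FNR rasters)
#'
#' @param grid A [grid_spec()].
#' @param dates Contiguous `Date` vector.
#' @param fnr `[n_lat, n_lon, n_dates]` array of false negative rates in
#'   `[0, 1]`; `NA` marks cells without predictions.
#' @export
risk_map_stack <- function(grid, dates, fnr) {
  dates <- as.Date(dates)
  if (length(dates) > 1 && any(diff(dates) != 1))
    stop("risk stack date index has gaps")
  d <- dim(fnr)
  if (is.null(d) || length(d) != 3 ||
      d[1] != grid$n_lat || d[2] != grid$n_lon || d[3] != length(dates))
    stop("fnr array shape does not match grid/dates")
  rng <- range(fnr, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    stop("FNR values must lie in [0, 1]")
  structure(list(grid = grid, dates = dates, fnr = fnr),
            class = "risk_map_stack")
}

#' @export
print.risk_map_stack <- function(x, ...) {
  cat(sprintf("<risk_map_stack> %d x %d cells, %d dates (%s .. %s)\n",
              x$grid$n_lat, x$grid$n_lon, length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)])))
  invisible(x)
}

# index of `date` within a cube/stack date vector, or NA
date_index <- function(dates, date) {
  match(as.Date(date), dates)
}
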