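# File I/O: observation CSVs, raster stacks as per-day float32 TIFF
# directories with a JSON sidecar (grid geometry + units), long-format CSV,
# and population rasters. All rasters are stored row 1 = southernmost
# latitude band, matching the in-memory convention.

grid_to_list <- function(grid) {
  grid[c("lat_min", "lat_max", "lon_min", "lon_max",
         "cell_size_lat", "cell_size_lon")]
}

grid_from_list <- function(x) {
  grid_spec(x$lat_min, x$lat_max, x$lon_min, x$lon_max,
            x$cell_size_lat, x$cell_size_lon)
}

write_sidecar <- function(path, grid, extra = list()) {
  jsonlite::write_json(c(list(grid = grid_to_list(grid)), extra),
                       file.path(path, "grid.json"), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  f <- file.path(path, "grid.json")
  if (!file.exists(f)) stop("missing grid.json sidecar in ", path)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

write_raster_tif <- function(m, file, grid = NULL) {
  write_geotiff(m, file, grid)
}

read_raster_tif <- function(file) {
  read_geotiff(file)
}

#' Read point observation records from CSV
#'
#' Expects a header `species,date,latitude,longitude` (ISO-8601 dates).
#' Rows are validated and snapped to grid cells; malformed rows (bad date,
#' latitude outside `[-90, 90]`, coordinates outside the grid) are skipped
#' and counted. If `dates` and `seq_len` are supplied, rows whose date does
#' not leave `seq_len` days of climate history inside the date index are
#' skipped with reason "insufficient history".
#'
#' @param path CSV file path.
#' @param grid A [grid_spec()] used for snapping.
#' @param dates Optional climate-cube date index for the history check.
#' @param seq_len Optional sequence length (days) for the history check.
#' @return An `observation_table` data frame with columns `species`, `date`,
#'   `lat`, `lon`, `label` (all 1 = presence), `cell`; attribute `skipped`
#'   is a named count vector of skip reasons.
#' @export
read_observations <- function(path, grid, dates = NULL, seq_len = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "date", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("observations CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("observations CSV is empty")
  skipped <- c(bad_date = 0L, bad_coord = 0L, insufficient_history = 0L)

  d <- suppressWarnings(as.Date(as.character(df$date)))
  bad <- is.na(d)
  skipped["bad_date"] <- sum(bad)
  lat <- suppressWarnings(as.numeric(df$latitude))
  lon <- suppressWarnings(as.numeric(df$longitude))
  lon_n <- normalize_lon(lon)
  tol <- 1e-9
  badc <- !bad & (is.na(lat) | is.na(lon) | lat < -90 | lat > 90 |
                    lat < grid$lat_min - tol | lat > grid$lat_max + tol |
                    lon_n < grid$lon_min - tol | lon_n > grid$lon_max + tol)
  skipped["bad_coord"] <- sum(badc)
  keep <- !bad & !badc
  if (!is.null(dates) && !is.null(seq_len)) {
    dates <- as.Date(dates)
    hist_ok <- d >= dates[1] + seq_len & d <= dates[length(dates)]
    skipped["insufficient_history"] <- sum(keep & !hist_ok)
    keep <- keep & hist_ok
  }
  if (sum(skipped) > 0)
    warning(sum(skipped), " observation row(s) skipped (",
            paste(sprintf("%s: %d", names(skipped)[skipped > 0],
                          skipped[skipped > 0]), collapse = ", "), ")")
  out <- data.frame(species = as.character(df$species)[keep],
                    date = d[keep], lat = lat[keep], lon = lon_n[keep],
                    label = 1L, stringsAsFactors = FALSE)
  out$cell <- if (nrow(out)) snap_to_cell(out$lat, out$lon, grid) else integer(0)
  attr(out, "skipped") <- skipped
  class(out) <- c("observation_table", "data.frame")
  out
}

#' Read a daily climate cube from a per-day TIFF directory
#'
#' Layout: `<path>/<var>/<YYYY-MM-DD>.tif` with a `<path>/grid.json` sidecar
#' describing the grid and per-variable units. Variables whose sidecar units
#' are `"K"` are converted to deg C on load. A gap in any variable's date
#' sequence is a hard error naming the missing date(s).
#'
#' @param path Directory written by [write_climate()] (or following the same
#'   convention).
#' @param vars Variables to load (default: all subdirectories).
#' @return A [climate_cube()].
#' @export
read_climate <- function(path, vars = NULL) {
  side <- read_sidecar(path)
  grid <- grid_from_list(side$grid)
  if (is.null(vars)) {
    vars <- list.dirs(path, recursive = FALSE, full.names = FALSE)
    if (!length(vars)) stop("no variable subdirectories under ", path)
  }
  units <- side$units
  all_dates <- NULL
  arrs <- list()
  for (v in vars) {
    vd <- file.path(path, v)
    files <- sort(list.files(vd, pattern = "^\\d{4}-\\d{2}-\\d{2}\\.tif$"))
    if (!length(files)) stop("no daily TIFFs for variable ", v)
    d <- as.Date(sub("\\.tif$", "", files))
    full <- seq(min(d), max(d), by = "day")
    missing <- setdiff(format(full), format(d))
    if (length(missing))
      stop("date gap in variable '", v, "': missing ",
           paste(utils::head(missing, 5), collapse = ", "))
    if (is.null(all_dates)) all_dates <- d
    else if (!identical(format(all_dates), format(d)))
      stop("variables cover different date ranges")
    a <- array(NA_real_, c(grid$n_lat, grid$n_lon, length(d)))
    for (i in seq_along(files)) {
      m <- read_raster_tif(file.path(vd, files[i]))
      if (!all(dim(m) == c(grid$n_lat, grid$n_lon)))
        stop("raster shape mismatch in ", file.path(vd, files[i]))
      a[, , i] <- m
    }
    if (!is.null(units[[v]]) && identical(units[[v]], "K")) a <- a - 273.15
    arrs[[v]] <- a
  }
  cls <- if (all(vars %in% DERIVED_VARS) && length(vars) <= 5) "derived_cube" else "climate_cube"
  climate_cube(grid, all_dates, arrs, class = cls)
}

#' Write a climate (or derived) cube to a per-day TIFF directory
#'
#' Inverse of [read_climate()]; values are stored as float32.
#'
#' @param cube A [climate_cube()] or derived cube.
#' @param path Output directory (created).
#' @param units Optional named list of unit strings recorded in the sidecar.
#' @export
write_climate <- function(cube, path, units = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_sidecar(path, cube$grid, list(units = units))
  for (v in names(cube$vars)) {
    vd <- file.path(path, v)
    dir.create(vd, showWarnings = FALSE)
    for (i in seq_along(cube$dates))
      write_raster_tif(cube$vars[[v]][, , i],
                       file.path(vd, paste0(format(cube$dates[i]), ".tif")),
                       cube$grid)
  }
  invisible(path)
}

#' Write / read daily FNR risk maps
#'
#' `format = "geotiff"` writes one float32 TIFF per day under `<path>/fnr/`
#' with a `grid.json` sidecar (lossless for float32 payloads);
#' `format = "csv"` writes a long-format CSV with columns
#' `date, lat, lon, fnr` (one row per cell-date). NetCDF output is not
#' supported by this build and raises an error.
#'
#' @param stack A [risk_map_stack()].
#' @param path Output directory (geotiff) or file path (csv).
#' @param format `"geotiff"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_risk_maps <- function(stack, path, format = c("geotiff", "csv")) {
  if (length(format) == 1 && identical(format, "netcdf"))
    stop("NetCDF output is not supported; use 'geotiff' or 'csv'")
  format <- match.arg(format)
  if (format == "geotiff") {
    dir.create(file.path(path, "fnr"), recursive = TRUE, showWarnings = FALSE)
    write_sidecar(path, stack$grid)
    for (i in seq_along(stack$dates))
      write_raster_tif(stack$fnr[, , i],
                       file.path(path, "fnr", paste0(format(stack$dates[i]), ".tif")),
                       stack$grid)
  } else {
    ctr <- cell_center(stack$grid, seq_len(n_cells(stack$grid)))
    rows <- do.call(rbind, lapply(seq_along(stack$dates), function(i) {
      data.frame(date = format(stack$dates[i]), lat = ctr[, "lat"],
                 lon = ctr[, "lon"], fnr = as.vector(stack$fnr[, , i]))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_risk_maps
#' @export
read_risk_maps <- function(path) {
  side <- read_sidecar(path)
  grid <- grid_from_list(side$grid)
  files <- sort(list.files(file.path(path, "fnr"),
                           pattern = "^\\d{4}-\\d{2}-\\d{2}\\.tif$"))
  if (!length(files)) stop("no FNR TIFFs under ", path)
  dates <- as.Date(sub("\\.tif$", "", files))
  a <- array(NA_real_, c(grid$n_lat, grid$n_lon, length(dates)))
  for (i in seq_along(files)) {
    a[, , i] <- read_raster_tif(file.path(path, "fnr", files[i]))
  }
  risk_map_stack(grid, dates, a)
}

#' Write / read a land mask as TIFF + sidecar
#' @param mask A [land_mask()].
#' @param path Output directory.
#' @export
write_land_mask <- function(mask, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_sidecar(path, mask$grid)
  write_raster_tif(mask$is_land * 1, file.path(path, "land.tif"), mask$grid)
  invisible(path)
}

#' @rdname write_land_mask
#' @export
read_land_mask <- function(path) {
  side <- read_sidecar(path)
  grid <- grid_from_list(side$grid)
  land_mask(grid, read_raster_tif(file.path(path, "land.tif")) > 0.5)
}

#' Write / read a population grid (one TIFF per census year)
#' @param pop A [population_grid()].
#' @param path Output directory; files are `pop_<year>.tif`.
#' @export
write_population <- function(pop, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_sidecar(path, pop$grid, list(census_years = pop$census_years))
  for (y in names(pop$counts))
    write_raster_tif(pop$counts[[y]], file.path(path, paste0("pop_", y, ".tif")),
                     pop$grid)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  side <- read_sidecar(path)
  grid <- grid_from_list(side$grid)
  years <- sort(as.integer(side$census_years))
  counts <- lapply(years, function(y)
    read_raster_tif(file.path(path, paste0("pop_", y, ".tif"))))
  population_grid(grid, years, counts)
}

#' Resample a population grid to a target grid, conserving persons
#'
#' Each source cell's persons are distributed over the target cells it
#' overlaps in proportion to the overlapped fraction of the source cell's
#' lat-lon rectangle (area-weighted sum on the degree grid). Total persons
#' are conserved whenever the target extent covers the source extent.
#'
#' @param pop A [population_grid()].
#' @param target A [grid_spec()].
#' @return A [population_grid()] on `target`.
#' @export
resample_population <- function(pop, target) {
  if (grids_identical(pop$grid, target)) return(pop)
  ov <- function(n_s, min_s, cs_s, n_t, min_t, cs_t) {
    # overlap-length matrix [n_t, n_s], as fraction of the source cell size
    s_lo <- min_s + (seq_len(n_s) - 1) * cs_s; s_hi <- s_lo + cs_s
    t_lo <- min_t + (seq_len(n_t) - 1) * cs_t; t_hi <- t_lo + cs_t
    m <- outer(t_hi, s_hi, pmin) - outer(t_lo, s_lo, pmax)
    m[m < 0] <- 0
    m / cs_s
  }
  A <- ov(pop$grid$n_lat, pop$grid$lat_min, pop$grid$cell_size_lat,
          target$n_lat, target$lat_min, target$cell_size_lat)
  B <- ov(pop$grid$n_lon, pop$grid$lon_min, pop$grid$cell_size_lon,
          target$n_lon, target$lon_min, target$cell_size_lon)
  counts <- lapply(pop$counts, function(m) A %*% m %*% t(B))
  population_grid(target, pop$census_years, counts)
}
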