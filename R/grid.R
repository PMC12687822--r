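# Grid geometry: regular lat/lon grids with a cell-center convention.

#' Define a regular latitude/longitude grid
#'
#' A `grid_spec` describes a regular lat/lon raster by its outer extent and
#' cell size. Cells are registered on their centers: the center of cell
#' `(i, j)` is at `lat_min + (i - 0.5) * cell_size_lat` and
#' `lon_min + (j - 0.5) * cell_size_lon`. With the default 0.25-degree cells
#' and extents at multiples of 0.25 this reproduces ERA5-style registration.
#'
#' @param lat_min,lat_max,lon_min,lon_max Outer extent in degrees. Longitudes
#'   are normalized to `[-180, 180)`.
#' @param cell_size_lat,cell_size_lon Cell size in degrees (default 0.25).
#' @return An object of class `grid_spec` with fields `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max`, `cell_size_lat`, `cell_size_lon`, `n_lat`, `n_lon`.
#' @examples
#' g <- grid_spec(-90, 90, -180, 180, 4.5, 4.5)
#' g$n_lat  # 40
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max,
                      cell_size_lat = 0.25, cell_size_lon = 0.25) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max))
  if (cell_size_lat <= 0 || cell_size_lon <= 0)
    stop("cell sizes must be positive")
  if (lat_max <= lat_min || lon_max <= lon_min)
    stop("extent must be non-empty (max > min)")
  n_lat <- (lat_max - lat_min) / cell_size_lat
  n_lon <- (lon_max - lon_min) / cell_size_lon
  if (abs(n_lat - round(n_lat)) > 1e-6 || abs(n_lon - round(n_lon)) > 1e-6)
    stop("extent must be an exact multiple of the cell size")
  n_lat <- as.integer(round(n_lat))
  n_lon <- as.integer(round(n_lon))
  g <- structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = normalize_lon(lon_min), lon_max = lon_max,
    cell_size_lat = cell_size_lat, cell_size_lon = cell_size_lon,
    n_lat = n_lat, n_lon = n_lon), class = "grid_spec")
  lat_c <- grid_lats(g)
  lon_c <- grid_lons(g)
  if (any(lat_c < -90) || any(lat_c > 90))
    stop("cell centers must lie within [-90, 90]")
  if (any(lon_c < -180) || any(lon_c >= 180))
    stop("cell centers must lie within [-180, 180)")
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g] x lon [%g, %g], cell %g x %g deg\n",
              x$n_lat, x$n_lon, x$lat_min, x$lat_max, x$lon_min, x$lon_max,
              x$cell_size_lat, x$cell_size_lon))
  invisible(x)
}

#' Normalize longitudes to [-180, 180)
#' @param lon Numeric vector of longitudes in degrees.
#' @return Longitudes wrapped into `[-180, 180)`.
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Cell-center latitudes / longitudes of a grid
#' @param grid A [grid_spec()].
#' @return Numeric vector of cell-center coordinates, south-to-north
#'   (`grid_lats`) or west-to-east (`grid_lons`).
#' @export
grid_lats <- function(grid) grid$lat_min + (seq_len(grid$n_lat) - 0.5) * grid$cell_size_lat

#' @rdname grid_lats
#' @export
grid_lons <- function(grid) grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$cell_size_lon

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @export
n_cells <- function(grid) grid$n_lat * grid$n_lon

# Cell ids are column-major over (lat, lon): id = row + (col - 1) * n_lat,
# matching R's array layout so a raster matrix indexed by id is a plain
# vector lookup.

#' Convert between cell ids and (row, col) indices
#'
#' Rows index latitude south-to-north, columns index longitude west-to-east.
#' @param grid A [grid_spec()].
#' @param cell Integer cell id(s).
#' @return `cell_rowcol`: a two-column integer matrix (`row`, `col`);
#'   `rowcol_cell`: integer cell id(s).
#' @export
cell_rowcol <- function(grid, cell) {
  stopifnot(all(cell >= 1), all(cell <= n_cells(grid)))
  cbind(row = as.integer((cell - 1L) %% grid$n_lat + 1L),
        col = as.integer((cell - 1L) %/% grid$n_lat + 1L))
}

#' @rdname cell_rowcol
#' @param row,col Integer row/column indices.
#' @export
rowcol_cell <- function(grid, row, col) {
  as.integer(row + (col - 1L) * grid$n_lat)
}

#' Cell-center coordinates for cell ids
#' @param grid A [grid_spec()].
#' @param cell Integer cell id(s).
#' @return Two-column matrix with `lat` and `lon` of each cell center.
#' @export
cell_center <- function(grid, cell) {
  rc <- cell_rowcol(grid, cell)
  cbind(lat = grid$lat_min + (rc[, "row"] - 0.5) * grid$cell_size_lat,
        lon = grid$lon_min + (rc[, "col"] - 0.5) * grid$cell_size_lon)
}

#' Snap points to their nearest grid cell
#'
#' Returns, for each point, the id of the cell whose center is nearest in
#' plain lat/lon Euclidean distance (appropriate for a regular grid; not
#' great-circle). Ties are broken deterministically toward the lower row,
#' then the lower column index.
#'
#' @param lat,lon Point coordinates in degrees (vectors recycled to a common
#'   length). Longitudes are normalized to `[-180, 180)` first.
#' @param grid A [grid_spec()].
#' @return Integer vector of cell ids.
#' @export
snap_to_cell <- function(lat, lon, grid) {
  lon <- normalize_lon(lon)
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  tol <- 1e-9
  if (any(lat < grid$lat_min - tol | lat > grid$lat_max + tol))
    stop("latitude outside grid extent")
  if (any(lon < grid$lon_min - tol | lon > grid$lon_max + tol))
    stop("longitude outside grid extent")
  # nearest center along each axis; ties go to the lower index
  snap1 <- function(x, x0, cs, nmax) {
    f <- (x - (x0 + cs / 2)) / cs      # 0 at first center
    i <- ceiling(f - 0.5)              # tie (f = k + 0.5) floors to k
    pmin(pmax(as.integer(i) + 1L, 1L), nmax)
  }
  r <- snap1(lat, grid$lat_min, grid$cell_size_lat, grid$n_lat)
  c <- snap1(lon, grid$lon_min, grid$cell_size_lon, grid$n_lon)
  rowcol_cell(grid, r, c)
}

#' Test two grids for geometric equality
#' @param a,b [grid_spec()] objects.
#' @param tol Numeric tolerance on extents and cell sizes.
#' @export
grids_identical <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lat_min - b$lat_min, a$lat_max - b$lat_max,
            a$lon_min - b$lon_min, a$lon_max - b$lon_max,
            a$cell_size_lat - b$cell_size_lat,
            a$cell_size_lon - b$cell_size_lon)) < tol) &&
    a$n_lat == b$n_lat && a$n_lon == b$n_lon
}
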