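# Minimal float32 GeoTIFF writer.
#
# No installed R package writes floating-point TIFF samples (the `tiff`
# package encodes [0,1]-scaled integers only), so the writer emits the
# format directly: little-endian, single-image, single-strip, uncompressed
# grayscale with SampleFormat = IEEE float, plus the ModelPixelScale and
# ModelTiepoint GeoTIFF tags. Reading goes through libtiff via
# `tiff::readTIFF`, which handles float samples natively; round-trips are
# exact for float32 payloads. Rasters are stored north-up (first image row
# = northernmost band) as GIS tools expect and flipped to the package's
# south-first matrix convention in memory.

#' Write a raster matrix as a float32 GeoTIFF
#'
#' @param m Numeric `[n_lat, n_lon]` matrix, row 1 = southernmost band
#'   (the file itself is written north-up). `NA` is stored as NaN.
#' @param file Output path.
#' @param grid Optional [grid_spec()]; when given, ModelPixelScale and
#'   ModelTiepoint tags georeference the raster (tiepoint at the grid's
#'   north-west corner).
#' @return `file`, invisibly.
#' @export
write_geotiff <- function(m, file, grid = NULL) {
  stopifnot(is.matrix(m))
  if (!is.null(grid) && !all(dim(m) == c(grid$n_lat, grid$n_lon)))
    stop("matrix shape does not match grid")
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # north-up on disk
  h <- nrow(m); w <- ncol(m)
  data <- as.numeric(t(m))
  data[is.na(data)] <- NaN
  n_bytes <- 4L * h * w
  tags <- list(
    c(256L, 4L, 1L, w),        # ImageWidth
    c(257L, 4L, 1L, h),        # ImageLength
    c(258L, 3L, 1L, 32L),      # BitsPerSample
    c(259L, 3L, 1L, 1L),       # Compression: none
    c(262L, 3L, 1L, 1L),       # Photometric: BlackIsZero
    c(273L, 4L, 1L, NA),       # StripOffsets (filled below)
    c(277L, 3L, 1L, 1L),       # SamplesPerPixel
    c(278L, 4L, 1L, h),        # RowsPerStrip
    c(279L, 4L, 1L, n_bytes),  # StripByteCounts
    c(339L, 3L, 1L, 3L)        # SampleFormat: IEEE float
  )
  geo <- NULL
  if (!is.null(grid)) {
    tags <- c(tags, list(c(33550L, 12L, 3L, NA), c(33922L, 12L, 6L, NA)))
    geo <- list(ps = c(grid$cell_size_lon, grid$cell_size_lat, 0),
                tp = c(0, 0, 0, grid$lon_min, grid$lat_max, 0))
  }
  tags <- tags[order(vapply(tags, `[`, numeric(1), 1))]
  n_tags <- length(tags)
  ifd_off <- 8L
  extra_off <- ifd_off + 2L + 12L * n_tags + 4L
  ps_off <- extra_off; tp_off <- ps_off + 24L
  data_off <- if (is.null(geo)) extra_off else tp_off + 48L
  con <- base::file(file, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(n_tags, con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    val <- switch(as.character(tg[1]),
                  "273" = data_off, "33550" = ps_off, "33922" = tp_off,
                  tg[4])
    if (tg[2] == 3L) {  # SHORT packed left-justified in the 4-byte slot
      writeBin(as.integer(val), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(val), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no further IFDs
  if (!is.null(geo)) {
    writeBin(as.numeric(geo$ps), con, size = 8, endian = "little")
    writeBin(as.numeric(geo$tp), con, size = 8, endian = "little")
  }
  writeBin(data, con, size = 4, endian = "little")
  invisible(file)
}

#' Read a single-band float GeoTIFF as a raster matrix
#'
#' @param file TIFF path (float32 grayscale; anything libtiff reads works).
#' @return Numeric matrix, row 1 = southernmost band; NaN becomes `NA`.
#' @export
read_geotiff <- function(file) {
  m <- tiff::readTIFF(file)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  m[is.nan(m)] <- NA
  m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first
}
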