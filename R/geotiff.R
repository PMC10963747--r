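#' Rasters on a grid
#'
#' An `et_raster` couples numeric values with their [et_grid()] georeference.
#' Values are a matrix (`n_rows x n_cols`, single band) or a 3-D array
#' (`n_rows x n_cols x n_bands`, e.g. band = month). Missing cells are `NA`.
#'
#' @param values Numeric matrix or 3-D array of cell values.
#' @param grid An [et_grid()] whose dimensions match `values`.
#' @param band_names Optional character names for the band dimension.
#' @return An object of class `et_raster`.
#' @export
et_raster <- function(values, grid, band_names = NULL) {
  d <- dim(values)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("values must be a matrix or a 3-D array")
  if (d[1] != grid$n_rows || d[2] != grid$n_cols)
    stop(sprintf("values are %d x %d but grid is %d x %d",
                 d[1], d[2], grid$n_rows, grid$n_cols))
  if (!is.null(band_names)) {
    nb <- if (length(d) == 3L) d[3] else 1L
    if (length(band_names) != nb) stop("band_names length must match bands")
  }
  structure(list(values = values, grid = grid, band_names = band_names),
            class = "et_raster")
}

#' @export
print.et_raster <- function(x, ...) {
  d <- dim(x$values)
  nb <- if (length(d) == 3L) d[3] else 1L
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<et_raster> %d band(s) on %s; range [%g, %g], %d NA\n",
              nb, format(x$grid), rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

n_bands <- function(r) { d <- dim(r$values); if (length(d) == 3L) d[3] else 1L }

raster_band <- function(r, i) {
  if (length(dim(r$values)) == 3L) r$values[, , i] else r$values
}

## ---- minimal GeoTIFF codec -------------------------------------------------
## Uncompressed, little-endian, one sample per pixel, IEEE float64 samples,
## one strip per band, georeference via ModelPixelScale + ModelTiepoint and a
## minimal GeoKeyDirectory. The installed raster stacks cannot carry physical
## units losslessly, hence this self-contained writer/reader pair. The reader
## also accepts float32 data and multi-strip layouts.

.tif <- list(SHORT = 3L, LONG = 4L, DOUBLE = 12L, ASCII = 2L)
.tif_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
               `11` = 4L, `12` = 8L)

.u16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
.u32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
.f64 <- function(v) writeBin(as.numeric(v), raw(), size = 8, endian = "little")

# One 12-byte IFD entry. `value` is a raw vector already encoded; if it is
# longer than 4 bytes the caller must have stored it externally and pass the
# offset instead.
.ifd_entry <- function(tag, type, count, value_raw = NULL, offset = NULL) {
  out <- c(.u16(tag), .u16(type), .u32(count))
  if (!is.null(offset)) {
    c(out, .u32(offset))
  } else {
    v <- value_raw
    if (length(v) > 4L) stop("inline IFD value too long")
    c(out, v, raw(4L - length(v)))
  }
}

#' Write a raster to a GeoTIFF file
#'
#' Writes uncompressed IEEE float64 samples (lossless for R doubles, so a
#' write/read round trip is bit-exact), one TIFF directory per band, with
#' `ModelPixelScaleTag`/`ModelTiepointTag` carrying the grid georeference.
#' `NA` cells are stored as NaN.
#'
#' @param raster An [et_raster()] (or a plain matrix plus `grid`).
#' @param path Output file path.
#' @param grid Required when `raster` is a bare matrix/array.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(raster, path, grid = NULL) {
  if (!inherits(raster, "et_raster")) {
    if (is.null(grid)) stop("grid is required when raster is not an et_raster")
    raster <- et_raster(raster, grid)
  }
  g <- raster$grid
  nb <- n_bands(raster)
  nr <- g$n_rows; nc <- g$n_cols
  strip_bytes <- nr * nc * 8L

  geo_scale <- .f64(c(g$pixel_size, g$pixel_size, 0))
  geo_tie   <- .f64(c(0, 0, 0, g$origin_x, g$origin_y, 0))
  # GeoKeyDirectory: version 1.1.0, 1 key: GTRasterTypeGeoKey = PixelIsArea
  geo_keys  <- .u16(c(1L, 1L, 0L, 1L, 1025L, 0L, 1L, 1L))

  header_len <- 8L
  strips_at <- header_len + (seq_len(nb) - 1L) * strip_bytes
  ext_at <- header_len + nb * strip_bytes
  scale_at <- ext_at
  tie_at   <- scale_at + length(geo_scale)
  keys_at  <- tie_at + length(geo_tie)
  ifd0_at  <- keys_at + length(geo_keys)
  n_entries <- 13L
  ifd_len <- 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)          # "II"
  writeBin(.u16(42L), con)
  writeBin(.u32(ifd0_at), con)
  for (b in seq_len(nb)) {
    m <- raster_band(raster, b)
    v <- as.numeric(t(m))                                # row-major
    v[is.na(v)] <- NaN
    writeBin(v, con, size = 8, endian = "little")
  }
  writeBin(geo_scale, con); writeBin(geo_tie, con); writeBin(geo_keys, con)
  for (b in seq_len(nb)) {
    next_ifd <- if (b < nb) ifd0_at + b * ifd_len else 0L
    entries <- c(
      .ifd_entry(256L, .tif$LONG, 1L, .u32(nc)),               # ImageWidth
      .ifd_entry(257L, .tif$LONG, 1L, .u32(nr)),               # ImageLength
      .ifd_entry(258L, .tif$SHORT, 1L, .u16(64L)),             # BitsPerSample
      .ifd_entry(259L, .tif$SHORT, 1L, .u16(1L)),              # no compression
      .ifd_entry(262L, .tif$SHORT, 1L, .u16(1L)),              # BlackIsZero
      .ifd_entry(273L, .tif$LONG, 1L, .u32(strips_at[b])),     # StripOffsets
      .ifd_entry(277L, .tif$SHORT, 1L, .u16(1L)),              # SamplesPerPixel
      .ifd_entry(278L, .tif$LONG, 1L, .u32(nr)),               # RowsPerStrip
      .ifd_entry(279L, .tif$LONG, 1L, .u32(strip_bytes)),      # StripByteCounts
      .ifd_entry(339L, .tif$SHORT, 1L, .u16(3L)),              # IEEE float
      .ifd_entry(33550L, .tif$DOUBLE, 3L, offset = scale_at),  # ModelPixelScale
      .ifd_entry(33922L, .tif$DOUBLE, 6L, offset = tie_at),    # ModelTiepoint
      .ifd_entry(34735L, .tif$SHORT, 8L, offset = keys_at)     # GeoKeyDirectory
    )
    writeBin(.u16(n_entries), con)
    writeBin(entries, con)
    writeBin(.u32(next_ifd), con)
  }
  invisible(path)
}

.rd_int <- function(bytes, at, size, n = 1L) {
  readBin(bytes[at + seq_len(size * n)], "integer", n = n, size = size,
          endian = "little", signed = size >= 4L)
}

.rd_vals <- function(bytes, type, count, entry_at) {
  sz <- .tif_size[[as.character(type)]]
  total <- sz * count
  at <- if (total <= 4L) entry_at + 8L else .rd_int(bytes, entry_at + 8L, 4L)
  src <- bytes[at + seq_len(total)]
  switch(as.character(type),
         `3` = readBin(src, "integer", n = count, size = 2, endian = "little",
                       signed = FALSE),
         `4` = readBin(src, "integer", n = count, size = 4, endian = "little"),
         `12` = readBin(src, "double", n = count, size = 8, endian = "little"),
         `2` = rawToChar(src[src != as.raw(0)]),
         stop("unsupported TIFF tag type: ", type))
}

#' Read a GeoTIFF file written by [write_geotiff()] (or compatible)
#'
#' Supports little-endian, uncompressed, single-sample images with IEEE
#' float32/float64 samples over any strip layout. NaN cells become `NA`.
#'
#' @param path Input file path.
#' @param crs_label Label to attach to the resulting grid.
#' @return An [et_raster()].
#' @export
read_geotiff <- function(path, crs_label = "local-projected-m") {
  if (!file.exists(path)) stop("missing file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (!(bytes[1] == 0x49 && bytes[2] == 0x49))
    stop("unsupported TIFF byte order (only little-endian 'II' is read): ",
         path)
  if (.rd_int(bytes, 2L, 2L) != 42L) stop("not a TIFF file: ", path)
  ifd_at <- .rd_int(bytes, 4L, 4L)

  bands <- list(); geo <- NULL
  while (ifd_at != 0L) {
    n_entries <- .rd_int(bytes, ifd_at, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      at <- ifd_at + 2L + (i - 1L) * 12L
      tag <- .rd_int(bytes, at, 2L)
      type <- .rd_int(bytes, at + 2L, 2L)
      count <- .rd_int(bytes, at + 4L, 4L)
      tags[[as.character(tag)]] <- .rd_vals(bytes, type, count, at)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF tag ", tag, " missing: ", path)
        default
      } else v
    }
    nc <- need(256L); nr <- need(257L)
    bits <- need(258L); comp <- need(259L, 1L)
    if (comp != 1L) stop("compressed TIFF not supported: ", path)
    if (need(277L, 1L) != 1L) stop("multi-sample TIFF not supported: ", path)
    sf <- need(339L, 1L)
    if (!(sf == 3L && bits %in% c(32L, 64L)))
      stop("only IEEE float32/float64 samples supported: ", path)
    offs <- need(273L); cnts <- need(279L)
    data <- unlist(lapply(seq_along(offs), function(k)
      bytes[offs[k] + seq_len(cnts[k])]), use.names = FALSE)
    v <- readBin(as.raw(data), "double", n = nr * nc, size = bits / 8L,
                 endian = "little")
    v[is.nan(v)] <- NA_real_
    bands[[length(bands) + 1L]] <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
    if (is.null(geo) && !is.null(tags[["33550"]]) && !is.null(tags[["33922"]])) {
      sc <- tags[["33550"]]; tp <- tags[["33922"]]
      if (abs(sc[1] - sc[2]) > 1e-9 * sc[1])
        stop("non-square pixels not supported: ", path)
      geo <- list(pixel_size = sc[1],
                  origin_x = tp[4] - tp[1] * sc[1],
                  origin_y = tp[5] + tp[2] * sc[2])
    }
    ifd_at <- .rd_int(bytes, ifd_at + 2L + n_entries * 12L, 4L)
  }
  if (is.null(geo)) stop("no georeference tags found: ", path)
  nr <- nrow(bands[[1]]); nc <- ncol(bands[[1]])
  g <- et_grid(geo$origin_x, geo$origin_y, geo$pixel_size, nr, nc, crs_label)
  vals <- if (length(bands) == 1L) bands[[1]] else
    array(unlist(bands, use.names = FALSE), dim = c(nr, nc, length(bands)))
  if (length(bands) > 1L)
    for (b in seq_along(bands)) vals[, , b] <- bands[[b]]
  et_raster(vals, g)
}

#' Read several raster layers aligned to a common grid
#'
#' Each file must carry the same georeference as `grid`; any mismatch fails
#' with a message naming the offending layer. Bands of multi-band files are
#' stacked in order.
#'
#' @param path_list Character vector of GeoTIFF paths.
#' @param grid The [et_grid()] every layer must match.
#' @return An [et_raster()] with one band per input band, named
#'   `<basename>#<band>`.
#' @export
read_raster_stack <- function(path_list, grid) {
  if (length(path_list) == 0L) stop("path_list is empty")
  layers <- list(); nms <- character()
  for (p in path_list) {
    if (!file.exists(p)) stop("missing file: ", p)
    r <- read_geotiff(p, crs_label = grid$crs_label)
    if (!grids_identical(r$grid, grid))
      stop(sprintf(
        "layer '%s' is not aligned to the target grid (layer %s vs target %s)",
        p, format(r$grid), format(grid)))
    for (b in seq_len(n_bands(r))) {
      layers[[length(layers) + 1L]] <- raster_band(r, b)
      nms <- c(nms, paste0(basename(p), "#", b))
    }
  }
  vals <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(layers)))
  for (i in seq_along(layers)) vals[, , i] <- layers[[i]]
  et_raster(vals, grid, band_names = nms)
}
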