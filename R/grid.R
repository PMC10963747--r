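#' Regular raster grid in projected coordinates
#'
#' A grid is the minimal georeference the pipeline needs: an upper-left
#' origin in projected meters, a square pixel size, and row/column counts.
#' Pixel indices are 0-based and row-major with the origin at the upper-left
#' corner; a cell's value refers to the cell center.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the upper-left corner
#'   of the upper-left pixel. `y` decreases downward (northing convention).
#' @param pixel_size Side length of a (square) pixel in meters; must be > 0.
#' @param n_rows,n_cols Grid dimensions; must be >= 1.
#' @param crs_label Free-text label for the projected CRS (not interpreted).
#' @return An object of class `et_grid`.
#' @export
et_grid <- function(origin_x, origin_y, pixel_size, n_rows, n_cols,
                    crs_label = "local-projected-m") {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!(pixel_size > 0)) stop("pixel_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size),
         n_rows = n_rows, n_cols = n_cols, crs_label = as.character(crs_label)),
    class = "et_grid")
}

#' @export
print.et_grid <- function(x, ...) {
  cat(sprintf("<et_grid> %d x %d pixels @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

#' @export
format.et_grid <- function(x, ...) {
  sprintf("%dx%d@%gm(%g,%g)", x$n_rows, x$n_cols, x$pixel_size,
          x$origin_x, x$origin_y)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    identical(a$crs_label, b$crs_label)
}

#' Pixel-center coordinates for 0-based row/column indices
#'
#' @param grid An [et_grid()].
#' @param row,col 0-based row and column indices (vectors, recycled).
#' @return A list with numeric vectors `x` and `y` of pixel centers (m).
#' @export
pixel_center <- function(grid, row, col) {
  list(x = grid$origin_x + (col + 0.5) * grid$pixel_size,
       y = grid$origin_y - (row + 0.5) * grid$pixel_size)
}

#' All pixel centers of a grid as a data.table
#'
#' Rows are emitted in row-major order (row 0 first), matching the memory
#' layout of raster values.
#'
#' @param grid An [et_grid()].
#' @return data.table with columns `row_id`, `col_id` (0-based), `x`, `y`.
#' @export
pixel_centers <- function(grid) {
  dt <- CJ(row_id = seq_len(grid$n_rows) - 1L,
           col_id = seq_len(grid$n_cols) - 1L)
  ctr <- pixel_center(grid, dt$row_id, dt$col_id)
  dt[, `:=`(x = ctr$x, y = ctr$y)]
  dt[]
}

#' Square-tile identifiers for spatial blocking or clustering
#'
#' Tiles are axis-aligned squares of side `tile_m` anchored at the grid
#' origin (or at `(anchor_x, anchor_y)`), used both for the 2 km train/test
#' blocks and for the 75 km standard-error clusters.
#'
#' @param x,y Point coordinates (m).
#' @param tile_m Tile side length (m); must be > 0.
#' @param anchor_x,anchor_y Tile lattice anchor; defaults to 0 so that ids
#'   only depend on absolute coordinates.
#' @return Character vector of tile ids, e.g. `"12_-3"`.
#' @export
tile_id <- function(x, y, tile_m, anchor_x = 0, anchor_y = 0) {
  if (!(tile_m > 0)) stop("tile_m must be > 0")
  ix <- floor((x - anchor_x) / tile_m)
  iy <- floor((anchor_y - y) / tile_m)  # y decreases downward
  paste0(ix, "_", iy)
}
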