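#' Build the regular analysis lattice
#'
#' Creates the regular latitude/longitude analysis grid on which all fields
#' live, with one synthetic "province" (region) label per cell. Regions
#' partition the lattice into contiguous rectangular blocks, which stand in
#' for administrative provinces in the per-region model fits.
#'
#' @param bounds numeric length 4: `c(lat_min, lat_max, lon_min, lon_max)`
#'   in degrees. The spans must be whole multiples of `resolution`.
#' @param resolution cell size in degrees (default 0.1).
#' @param n_regions number of rectangular regions (default 1).
#' @return A `grid_spec`: a tibble with one row per cell and columns
#'   `cell_id` (0-based, row-major with rows along latitude), `row`, `col`
#'   (0-based), `lat`, `lon` (cell centroids, degrees) and `region`
#'   (character label). Attributes `bounds`, `resolution`, `nrow`, `ncol`
#'   record the lattice geometry.
#' @examples
#' g <- make_grid(c(0, 1, 0, 1), resolution = 0.5)
#' nrow(g) # 4 cells
#' @export
make_grid <- function(bounds, resolution = 0.1, n_regions = 1L) {
  if (!is.numeric(bounds) || length(bounds) != 4L)
    stopf("`bounds` must be c(lat_min, lat_max, lon_min, lon_max)")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stopf("`resolution` must be a positive number of degrees")
  if (n_regions < 1L) stopf("`n_regions` must be >= 1")
  lat_span <- bounds[2L] - bounds[1L]
  lon_span <- bounds[4L] - bounds[3L]
  nr <- round(lat_span / resolution)
  nc <- round(lon_span / resolution)
  if (nr < 2L || nc < 2L) stopf("bounds must span at least 2 cells per axis")
  if (abs(nr * resolution - lat_span) > 1e-9 ||
      abs(nc * resolution - lon_span) > 1e-9)
    stopf("bounds spans must be whole multiples of `resolution`")

  row <- rep(0:(nr - 1L), each = nc)
  col <- rep(0:(nc - 1L), times = nr)
  blocks <- region_blocks(n_regions)
  row_block <- findInterval(row, seq(0, nr, length.out = blocks[1L] + 1L),
                            rightmost.closed = TRUE, left.open = FALSE)
  col_block <- findInterval(col, seq(0, nc, length.out = blocks[2L] + 1L),
                            rightmost.closed = TRUE, left.open = FALSE)
  region_idx <- (row_block - 1L) * blocks[2L] + col_block

  g <- tibble(
    cell_id = row * nc + col,
    row = row,
    col = col,
    lat = bounds[1L] + (row + 0.5) * resolution,
    lon = bounds[3L] + (col + 0.5) * resolution,
    region = paste0("R", region_idx)
  )
  structure(g,
            bounds = bounds, resolution = resolution,
            nrow = nr, ncol = nc,
            class = c("grid_spec", class(g)))
}

# Near-square factorisation a x b = n with a <= b (a = block rows).
region_blocks <- function(n) {
  a <- floor(sqrt(n))
  while (a > 1L && n %% a != 0L) a <- a - 1L
  c(a, n %/% a)
}

#' @export
print.grid_spec <- function(x, ...) {
  b <- attr(x, "bounds")
  cat(sprintf(
    "<grid_spec> %d x %d cells (%.3g deg), lat [%g, %g], lon [%g, %g], %d region(s)\n",
    attr(x, "nrow"), attr(x, "ncol"), attr(x, "resolution"),
    b[1], b[2], b[3], b[4], length(unique(x$region))))
  NextMethod()
}

#' Map points to grid cells
#'
#' Returns the `cell_id` of the cell containing each point, or `NA` for
#' points outside the bounding box. Points exactly on an interior edge go to
#' the higher-index cell; the top edges belong to the last row/column.
#'
#' @param grid a `grid_spec`.
#' @param lat,lon point coordinates in degrees.
#' @return integer vector of cell ids.
#' @export
cell_of_point <- function(grid, lat, lon) {
  b <- attr(grid, "bounds"); res <- attr(grid, "resolution")
  nr <- attr(grid, "nrow"); nc <- attr(grid, "ncol")
  r <- floor((lat - b[1L]) / res)
  c_ <- floor((lon - b[3L]) / res)
  r[lat == b[2L]] <- nr - 1L
  c_[lon == b[4L]] <- nc - 1L
  out <- r * nc + c_
  out[r < 0 | r >= nr | c_ < 0 | c_ >= nc] <- NA_integer_
  as.integer(out)
}
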