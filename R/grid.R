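# Equal-area plane and regular grids -----------------------------------------

# Authalic sphere radius (m): the sphere with the same surface area as the
# WGS84 ellipsoid, so planar areas computed after projection are true areas.
.R_AUTHALIC <- 6371007.2

#' Project geographic coordinates onto an equal-area plane
#'
#' Cylindrical equal-area projection on the authalic sphere (radius
#' 6,371,007.2 m), standard parallel 0 (Lambert): `x = R * lambda`,
#' `y = R * sin(phi)`.  Areas measured on this plane equal areas on the
#' sphere, which is what both extent-of-occurrence and area-of-occupancy
#' computations require.  Invertible for latitudes strictly inside the poles.
#'
#' @param lon,lat numeric vectors of longitude and latitude in decimal
#'   degrees (WGS84).
#' @return A two-column matrix with columns `x_m` and `y_m` (projected
#'   metres).
#' @examples
#' project_equal_area(1, 0)   # x about 111,195 m on the equator
#' @seealso [unproject_equal_area()]
#' @export
project_equal_area <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  cbind(x_m = .R_AUTHALIC * lon * pi / 180,
        y_m = .R_AUTHALIC * sin(lat * pi / 180))
}

#' Inverse of the equal-area projection
#'
#' @param x_m,y_m numeric vectors of projected metres.
#' @return A two-column matrix with columns `lon` and `lat` in degrees.
#' @export
unproject_equal_area <- function(x_m, y_m) {
  s <- y_m / .R_AUTHALIC
  if (any(abs(s) > 1 + 1e-12)) stop("y_m outside the projected sphere")
  s <- pmin(1, pmax(-1, s))
  cbind(lon = x_m / .R_AUTHALIC * 180 / pi,
        lat = asin(s) * 180 / pi)
}

#' Define a regular grid on the equal-area plane
#'
#' A grid is the common spatial frame of environmental layers, suitability
#' maps and occupancy counts.  Cell `(row, col)` covers
#' `x in [origin_x + (col-1)*cell_m, origin_x + col*cell_m)` and likewise in
#' `y` with `row`; rows increase with `y`.
#'
#' @param origin_x_m,origin_y_m coordinates (projected metres) of the grid's
#'   lower-left corner.
#' @param cell_m positive cell edge in metres (2000 for the IUCN 2-km
#'   occupancy reference scale).
#' @param n_rows,n_cols positive integer grid dimensions.
#' @param projection_tag free-text label for the plane the grid lives in.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x_m, origin_y_m, cell_m, n_rows, n_cols,
                      projection_tag = "cea_authalic_sp0") {
  stopifnot(is.numeric(cell_m), length(cell_m) == 1, cell_m > 0,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols))
  structure(
    list(origin_x_m = as.numeric(origin_x_m),
         origin_y_m = as.numeric(origin_y_m),
         cell_m = as.numeric(cell_m),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         projection_tag = projection_tag),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%g, %g) [%s]\n",
              x$n_rows, x$n_cols, x$cell_m, x$origin_x_m, x$origin_y_m,
              x$projection_tag))
  invisible(x)
}

# Row/col indices (1-based) of projected points; points outside the grid get
# NA in both columns.
grid_cell_of <- function(grid, x_m, y_m) {
  col <- floor((x_m - grid$origin_x_m) / grid$cell_m) + 1
  row <- floor((y_m - grid$origin_y_m) / grid$cell_m) + 1
  out <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[out] <- NA_real_
  row[out] <- NA_real_
  cbind(row = row, col = col)
}

# Centre coordinates (projected metres) of cells given by row/col vectors.
grid_cell_centre <- function(grid, row, col) {
  cbind(x_m = grid$origin_x_m + (col - 0.5) * grid$cell_m,
        y_m = grid$origin_y_m + (row - 0.5) * grid$cell_m)
}

# Area of one cell in km^2.
grid_cell_area_km2 <- function(grid) (grid$cell_m / 1000)^2
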