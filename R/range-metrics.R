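# EOO (minimum convex polygon) and AOO (2-km occupancy grid) -----------------

# Shoelace area of a polygon given vertex coordinates (not necessarily
# closed), in the units of the coordinates squared.
.shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull area in km^2 of points given in projected metres.  Collinear
# or near-collinear configurations (area below tol_km2) report 0.
.hull_area_km2 <- function(x_m, y_m, tol_km2 = 1e-6) {
  pts <- unique(cbind(x_m, y_m))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  a <- .shoelace_area(pts[h, 1] / 1000, pts[h, 2] / 1000)
  if (a < tol_km2) 0 else a
}

#' Extent of occurrence from occurrence points
#'
#' Area of the minimum convex polygon enclosing all records, computed on
#' the equal-area plane.  Degenerate configurations (fewer than three
#' distinct points, or all points collinear within an area tolerance of
#' 1e-6 km2) report 0; the criteria engine receives both EOO and AOO and
#' the IUCN convention EOO >= AOO is applied there, not here.
#'
#' @param set an `occurrence_set` with at least one record.
#' @return EOO in km2.
#' @examples
#' sq <- occurrence_set("sq", lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
#' eoo_from_points(sq)
#' @export
eoo_from_points <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  if (nrow(set$records) < 1) stop("empty occurrence set")
  xy <- project_equal_area(set$records$lon, set$records$lat)
  .hull_area_km2(xy[, 1], xy[, 2])
}

#' Area of occupancy from occurrence points
#'
#' Number of distinct occupied cells of a `cell_km` x `cell_km` grid on the
#' equal-area plane, times the cell area.  The IUCN reference scale is
#' 2 x 2 km, giving AOO as a multiple of 4 km2.  The grid is anchored at
#' the projected origin by default.
#'
#' @param set an `occurrence_set` with at least one record.
#' @param cell_km cell edge in km (default 2, the IUCN reference scale).
#' @param origin_x_m,origin_y_m grid anchor (projected metres), for
#'   sensitivity analyses of the arbitrary grid placement.
#' @return AOO in km2.
#' @export
aoo_from_points <- function(set, cell_km = 2, origin_x_m = 0, origin_y_m = 0) {
  stopifnot(inherits(set, "occurrence_set"), cell_km > 0)
  if (nrow(set$records) < 1) stop("empty occurrence set")
  xy <- project_equal_area(set$records$lon, set$records$lat)
  cx <- floor((xy[, 1] - origin_x_m) / (1000 * cell_km))
  cy <- floor((xy[, 2] - origin_y_m) / (1000 * cell_km))
  nrow(unique(cbind(cx, cy))) * cell_km^2
}

#' Binary range map
#'
#' A boolean grid marking cells predicted or known suitable; the raster
#' analogue of a point set for range-metric purposes.
#'
#' @param grid a [grid_spec()].
#' @param suitable logical matrix of dimension `n_rows` x `n_cols`
#'   (rows index `y`).
#' @return An object of class `range_map`.
#' @export
range_map <- function(grid, suitable) {
  stopifnot(inherits(grid, "grid_spec"), is.logical(suitable),
            nrow(suitable) == grid$n_rows, ncol(suitable) == grid$n_cols)
  suitable[is.na(suitable)] <- FALSE
  structure(list(grid = grid, suitable = suitable), class = "range_map")
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf("range_map: %d/%d suitable cells on %d x %d grid (%g m cells)\n",
              sum(x$suitable), length(x$suitable),
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_m))
  invisible(x)
}

# row/col matrix of suitable cells of a range_map
.map_cells <- function(map) which(map$suitable, arr.ind = TRUE)

#' Extent of occurrence from a binary range map
#'
#' Convex hull area over the centres of suitable cells, in km2.
#'
#' @param map a [range_map()] with at least one suitable cell.
#' @return EOO in km2.
#' @export
eoo_from_map <- function(map) {
  stopifnot(inherits(map, "range_map"))
  cells <- .map_cells(map)
  if (nrow(cells) == 0) stop("no suitable cell in map")
  ctr <- grid_cell_centre(map$grid, cells[, 1], cells[, 2])
  .hull_area_km2(ctr[, 1], ctr[, 2])
}

#' Area of occupancy from a binary range map
#'
#' Counts the `cell_km` x `cell_km` occupancy cells that contain the centre
#' of at least one suitable map cell, times the cell area.  An
#' all-unsuitable map has AOO 0.
#'
#' @param map a [range_map()].
#' @inheritParams aoo_from_points
#' @return AOO in km2.
#' @export
aoo_from_map <- function(map, cell_km = 2, origin_x_m = 0, origin_y_m = 0) {
  stopifnot(inherits(map, "range_map"), cell_km > 0)
  cells <- .map_cells(map)
  if (nrow(cells) == 0) return(0)
  ctr <- grid_cell_centre(map$grid, cells[, 1], cells[, 2])
  cx <- floor((ctr[, 1] - origin_x_m) / (1000 * cell_km))
  cy <- floor((ctr[, 2] - origin_y_m) / (1000 * cell_km))
  nrow(unique(cbind(cx, cy))) * cell_km^2
}

#' Bundle range metrics with their provenance
#'
#' @param eoo_km2,aoo_km2 nonnegative areas in km2.
#' @param basis how the range was obtained: direct observation
#'   (`"observed"`), distribution modelling (`"sdm"`), or `"unknown"`.
#' @param bound which bound of a modelled range the values are:
#'   `"lower_cl"`, `"consensus"`, or `"point_estimate"` for observed
#'   values.
#' @return An object of class `range_metrics`.
#' @export
range_metrics <- function(eoo_km2, aoo_km2,
                          basis = c("observed", "sdm", "unknown"),
                          bound = c("point_estimate", "consensus", "lower_cl")) {
  stopifnot(eoo_km2 >= 0, aoo_km2 >= 0)
  structure(list(eoo_km2 = as.numeric(eoo_km2),
                 aoo_km2 = as.numeric(aoo_km2),
                 basis = match.arg(basis), bound = match.arg(bound)),
            class = "range_metrics")
}

#' @export
print.range_metrics <- function(x, ...) {
  cat(sprintf("range_metrics (%s, %s): EOO %.1f km2, AOO %.1f km2\n",
              x$basis, x$bound, x$eoo_km2, x$aoo_km2))
  invisible(x)
}

#' Export the EOO hull or the occupied AOO cells as GeoJSON
#'
#' Geometries are written in WGS84 lon/lat order.  The hull is a Polygon;
#' occupancy cells form a MultiPolygon of squares on the equal-area plane
#' unprojected back to geographic coordinates.
#'
#' @param set an `occurrence_set`.
#' @param what `"eoo_hull"` or `"aoo_cells"`.
#' @inheritParams aoo_from_points
#' @return A GeoJSON string.
#' @export
range_geojson <- function(set, what = c("eoo_hull", "aoo_cells"),
                          cell_km = 2) {
  what <- match.arg(what)
  stopifnot(inherits(set, "occurrence_set"), nrow(set$records) >= 1)
  xy <- project_equal_area(set$records$lon, set$records$lat)
  if (what == "eoo_hull") {
    pts <- unique(cbind(xy[, 1], xy[, 2]))
    h <- if (nrow(pts) >= 3) grDevices::chull(pts[, 1], pts[, 2])
         else seq_len(nrow(pts))
    ring <- unproject_equal_area(pts[c(h, h[1]), 1], pts[c(h, h[1]), 2])
    geom <- list(type = "Polygon",
                 coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                   c(ring[i, 1], ring[i, 2]))))
  } else {
    s <- 1000 * cell_km
    cx <- unique(cbind(floor(xy[, 1] / s), floor(xy[, 2] / s)))
    polys <- lapply(seq_len(nrow(cx)), function(i) {
      x0 <- cx[i, 1] * s; y0 <- cx[i, 2] * s
      corners <- rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s),
                       c(x0, y0 + s), c(x0, y0))
      ll <- unproject_equal_area(corners[, 1], corners[, 2])
      list(lapply(seq_len(nrow(ll)), function(j) c(ll[j, 1], ll[j, 2])))
    })
    geom <- list(type = "MultiPolygon", coordinates = polys)
  }
  jsonlite::toJSON(list(type = "Feature",
                        properties = list(species = set$species_id,
                                          what = what),
                        geometry = geom),
                   auto_unbox = TRUE, digits = 10)
}
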