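# Patch restriction: keep only suitable patches holding observations --------

#' Label connected components of a binary range map
#'
#' Partitions suitable cells into maximal connected patches under 4- or
#' 8-connectivity (default 8: diagonal neighbours are contiguous).
#' Implemented as an iterative flood fill.
#'
#' @param map a [range_map()].
#' @param connectivity 4 (rook) or 8 (queen) adjacency.
#' @return Integer matrix of component ids (1, 2, ... in discovery order,
#'   scanning columns bottom-up); unsuitable cells are 0.
#' @export
label_components <- function(map, connectivity = 8) {
  stopifnot(inherits(map, "range_map"), connectivity %in% c(4, 8))
  s <- map$suitable
  nr <- nrow(s); nc <- ncol(s)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  next_id <- 0L
  for (start in which(s)) {
    if (labels[start] != 0L) next
    next_id <- next_id + 1L
    # depth-first fill from the seed cell, explicit preallocated stack
    stack <- integer(sum(s))
    stack[1L] <- start
    top <- 1L
    labels[start] <- next_id
    while (top > 0L) {
      cell <- stack[top]
      top <- top - 1L
      r0 <- ((cell - 1L) %% nr) + 1L
      c0 <- ((cell - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r1 <- r0 + dr[k]; c1 <- c0 + dc[k]
        if (r1 < 1L || r1 > nr || c1 < 1L || c1 > nc) next
        idx <- (c1 - 1L) * nr + r1
        if (s[idx] && labels[idx] == 0L) {
          labels[idx] <- next_id
          top <- top + 1L
          stack[top] <- idx
        }
      }
    }
  }
  labels
}

#' Restrict a range map to patches containing observation points
#'
#' The cells holding the (unjittered) records are first forced suitable --
#' observation points belong to the range by definition -- then every
#' connected patch that contains no record cell is removed.  This is the
#' step that trims a model's predicted range down to the habitat actually
#' reachable from known populations, often substantially reducing EOO and
#' AOO.
#'
#' @param map a [range_map()].
#' @param set an `occurrence_set`; at least one record must fall on the
#'   map's grid.
#' @param connectivity patch adjacency, 4 or 8 (default 8).
#' @return The restricted [range_map()].
#' @export
restrict_to_occupied_patches <- function(map, set, connectivity = 8) {
  stopifnot(inherits(map, "range_map"), inherits(set, "occurrence_set"))
  if (nrow(set$records) == 0) stop("no records to anchor patches")
  xy <- project_equal_area(set$records$lon, set$records$lat)
  rc <- grid_cell_of(map$grid, xy[, 1], xy[, 2])
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  if (nrow(rc) == 0) stop("no record falls on the map grid")
  forced <- map$suitable
  forced[cbind(rc[, 1], rc[, 2])] <- TRUE
  fmap <- range_map(map$grid, forced)
  labels <- label_components(fmap, connectivity = connectivity)
  keep_ids <- unique(labels[cbind(rc[, 1], rc[, 2])])
  keep_ids <- keep_ids[keep_ids != 0L]
  range_map(map$grid, matrix(labels %in% keep_ids,
                             nrow(labels), ncol(labels)))
}
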