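# Independent oracles and small fixture builders used across the suite.

# Gift-wrapping (Jarvis march) convex hull area, km^2, from projected
# metres.  Written independently of the package's chull/shoelace route.
oracle_hull_area_km2 <- function(x_m, y_m) {
  pts <- unique(cbind(x_m, y_m))
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  cur <- start
  repeat {
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- cross(pts[cur, ], pts[cand, ], pts[j, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) >
             sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- j
    }
    cur <- cand
    if (cur == start) break
    hull <- c(hull, cur)
    if (length(hull) > n) stop("gift wrap failed to close")
  }
  hx <- pts[hull, 1] / 1000
  hy <- pts[hull, 2] / 1000
  k <- length(hx)
  if (k < 3) return(0)
  j <- c(k, seq_len(k - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# Brute-force AOO: count distinct floor-indexed cells over projected points.
oracle_aoo_km2 <- function(lon, lat, cell_km = 2) {
  xy <- rangeprofile::project_equal_area(lon, lat)
  key <- unique(paste(floor(xy[, 1] / (1000 * cell_km)),
                      floor(xy[, 2] / (1000 * cell_km))))
  length(key) * cell_km^2
}

# Connected-component labels through igraph, an implementation route
# disjoint from the package's flood fill.  Returns a matrix of ids
# (renumbered by first appearance, column-major) with 0 for unsuitable.
oracle_label_components <- function(suitable, connectivity = 8) {
  nr <- nrow(suitable); nc <- ncol(suitable)
  idx <- which(suitable)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  pos <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  edges <- NULL
  for (a in seq_along(idx)) {
    dr <- abs(pos[, 1] - pos[a, 1])
    dc <- abs(pos[, 2] - pos[a, 2])
    nb <- if (connectivity == 8) which(dr <= 1 & dc <= 1)
          else which(dr + dc <= 1)
    nb <- nb[nb > a]
    if (length(nb)) edges <- rbind(edges, cbind(a, nb))
  }
  g <- igraph::make_graph(n = length(idx),
                          edges = if (is.null(edges)) integer(0)
                                  else as.vector(t(edges)),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  comp <- as.integer(factor(comp, levels = unique(comp)))
  out <- matrix(0L, nr, nc)
  out[idx] <- comp
  out
}

# Canonical renumbering so two labelings compare as partitions.
canon_labels <- function(m) {
  ids <- m[m != 0]
  m[m != 0] <- as.integer(factor(ids, levels = unique(ids)))
  m
}

# Tiny landscape + virtual species + records, for ensemble tests.
small_world <- function(seed, n = 30, n_presences = 12,
                        coefficients = c(0, 2, -1)) {
  cfg <- rangeprofile::simulation_config(
    seed = seed, n_rows = n, n_cols = n, n_layers = length(coefficients) - 1,
    smooth_sigma_cells = 3, true_coefficients = coefficients,
    n_presences = n_presences, uncertainty_km = 0.5)
  stack <- rangeprofile::make_landscape(cfg)
  vs <- rangeprofile::make_virtual_species(stack, cfg$true_coefficients,
                                           cfg$suitability_cut)
  set <- rangeprofile::sample_presences(vs, cfg$n_presences,
                                        cfg$uncertainty_km, seed = seed)
  list(cfg = cfg, stack = stack, vs = vs, set = set)
}

# Occurrence set straight from lon/lat vectors.
pts_set <- function(lon, lat, id = "sp", u = 0)
  rangeprofile::occurrence_set(id, lon, lat, uncertainty_km = u)

# Random occurrence set in a ~200 km box (degrees near the origin).
random_set <- function(n, seed) {
  set.seed(seed)
  pts_set(runif(n, -1, 1), runif(n, -1, 1))
}
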