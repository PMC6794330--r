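# Seeded synthetic landscapes, virtual species and point sets ----------------
#
# Stands in for real climate layers and field records: smoothed white-noise
# layers keep the spatial autocorrelation suitability models exploit, a
# virtual species defines a known truth to recover, and presence sampling
# proportional to suitability keeps AUC meaningfully below 1.

# 1-D Gaussian kernel, truncated at 3 sigma.
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge renormalization (matrix rows/cols).
.gauss_blur <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  if (length(k) == 1) return(m)
  conv1 <- function(v) {
    # convolve each column of v with k, renormalizing at the edges
    n <- nrow(v)
    half <- (length(k) - 1) / 2
    out <- matrix(0, n, ncol(v))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - 1 - half
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * v[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out / wsum
  }
  t(conv1(t(conv1(m))))
}

#' Simulation configuration
#'
#' The documented default configuration is the one the package's recovery
#' checks run under: a 100 x 100 grid of 1-km cells, three smoothed layers
#' (`sigma` = 5 cells), generating coefficients `(0, 2, -1, 0)` (intercept
#' then one per layer), suitability cut 0.5, 30 presences with 1 km
#' positional error.
#'
#' @param seed integer seed driving every random element.
#' @param n_rows,n_cols grid dimensions.
#' @param cell_m cell edge (m).
#' @param n_layers number of environmental layers.
#' @param smooth_sigma_cells Gaussian smoothing radius in cells.
#' @param true_coefficients numeric vector, intercept plus one coefficient
#'   per layer, defining the virtual species.
#' @param n_presences number of occurrence records to draw.
#' @param uncertainty_km positional error attached to each record.
#' @param suitability_cut threshold in (0,1) defining the true range.
#' @param origin_x_m,origin_y_m grid origin on the equal-area plane.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_rows = 100, n_cols = 100,
                              cell_m = 1000, n_layers = 3,
                              smooth_sigma_cells = 5,
                              true_coefficients = c(0, 2, -1, 0),
                              n_presences = 30, uncertainty_km = 1,
                              suitability_cut = 0.5,
                              origin_x_m = 0, origin_y_m = 0) {
  stopifnot(n_presences >= 1, smooth_sigma_cells >= 0,
            suitability_cut > 0, suitability_cut < 1,
            length(true_coefficients) == 1 + n_layers)
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic environmental landscape
#'
#' Independent smoothed-white-noise layers (Gaussian kernel, sigma in
#' cells), each standardized to mean 0 / sd 1 over valid cells.
#'
#' @param config a [simulation_config()].
#' @return An [env_stack()] with layers `env1`, `env2`, ...
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- grid_spec(config$origin_x_m, config$origin_y_m, config$cell_m,
                    config$n_rows, config$n_cols)
  layers <- .with_seed(config$seed, {
    lapply(seq_len(config$n_layers), function(i) {
      m <- matrix(stats::rnorm(config$n_rows * config$n_cols),
                  config$n_rows, config$n_cols)
      m <- .gauss_blur(m, config$smooth_sigma_cells)
      (m - mean(m)) / stats::sd(m)
    })
  })
  names(layers) <- paste0("env", seq_len(config$n_layers))
  env_stack(grid, layers)
}

#' Define a virtual species on a landscape
#'
#' Suitability is the logistic of a linear combination of the layers; the
#' true range is the cells at or above the suitability cut.
#'
#' @param stack an [env_stack()].
#' @param coefficients intercept plus one coefficient per layer.
#' @param cut suitability threshold in (0,1) defining the true range.
#' @return A list of class `virtual_species` with `true_suitability`
#'   (matrix), `true_range` (a [range_map()]), and `coefficients`.
#' @export
make_virtual_species <- function(stack, coefficients, cut = 0.5) {
  stopifnot(inherits(stack, "env_stack"))
  if (length(coefficients) != 1 + length(stack$layers))
    stop("need 1 + ", length(stack$layers), " coefficients")
  eta <- matrix(coefficients[1], stack$grid$n_rows, stack$grid$n_cols)
  for (i in seq_along(stack$layers))
    eta <- eta + coefficients[i + 1] * stack$layers[[i]]
  suit <- stats::plogis(eta)
  suit[!stack$valid_mask] <- NA
  tr <- suit >= cut
  tr[is.na(tr)] <- FALSE
  structure(list(true_suitability = suit,
                 true_range = range_map(stack$grid, tr),
                 coefficients = coefficients, cut = cut),
            class = "virtual_species")
}

#' Sample occurrence records from a virtual species
#'
#' Cells are drawn with probability proportional to suitability (with
#' replacement); each record is then placed uniformly within its cell and
#' stamped with the given positional error.
#'
#' @param vs a `virtual_species`.
#' @param n number of records.
#' @param uncertainty_km positional error radius attached to each record.
#' @param seed integer seed.
#' @param species_id id for the resulting set.
#' @return An `occurrence_set`.
#' @export
sample_presences <- function(vs, n, uncertainty_km, seed,
                             species_id = "virtual_species") {
  stopifnot(inherits(vs, "virtual_species"), n >= 1)
  suit <- vs$true_suitability
  grid <- vs$true_range$grid
  w <- as.vector(suit)
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("virtual species has zero total suitability")
  xy <- .with_seed(seed, {
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    row <- ((idx - 1L) %% nrow(suit)) + 1L
    col <- ((idx - 1L) %/% nrow(suit)) + 1L
    cbind(grid$origin_x_m + (col - 1 + stats::runif(n)) * grid$cell_m,
          grid$origin_y_m + (row - 1 + stats::runif(n)) * grid$cell_m)
  })
  ll <- unproject_equal_area(xy[, 1], xy[, 2])
  occurrence_set(species_id, ll[, 1], ll[, 2],
                 uncertainty_km = uncertainty_km)
}

#' Generate a cave-cluster point set
#'
#' Observed-basis fixtures in the style of cave-restricted (troglobiont)
#' species: `k` points displaced from a centre by an isotropic Gaussian
#' with standard deviation `spread_km` on the equal-area plane.
#'
#' @param k number of points.
#' @param centre_lon,centre_lat cluster centre in degrees.
#' @param spread_km per-axis Gaussian displacement sd in km.
#' @param seed integer seed.
#' @param species_id id for the resulting set.
#' @return An `occurrence_set` (uncertainty 0: cave entrances are exact).
#' @export
make_cave_points <- function(k, centre_lon, centre_lat, spread_km, seed,
                             species_id = "cave_species") {
  stopifnot(k >= 1, spread_km >= 0)
  c_xy <- project_equal_area(centre_lon, centre_lat)
  xy <- .with_seed(seed,
    cbind(c_xy[1] + stats::rnorm(k, 0, spread_km * 1000),
          c_xy[2] + stats::rnorm(k, 0, spread_km * 1000)))
  ll <- unproject_equal_area(xy[, 1], xy[, 2])
  occurrence_set(species_id, ll[, 1], ll[, 2], uncertainty_km = 0)
}
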