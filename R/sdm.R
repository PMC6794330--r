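# Presence-background ensemble suitability modelling -------------------------
#
# The ensemble propagates positional uncertainty: each run jitters every
# record within its stated error radius, thins to one presence per cell,
# refits the suitability model against a fresh background sample, and
# binarizes the prediction.  Runs are combined by an AUC-derived weight,
#   weight = max(0, AUC - 0.5)^2,
# so an uninformative run (AUC <= 0.5) contributes nothing and a perfect
# one contributes 0.25.  The weighted vote share per cell (the score map)
# is cut at 0.5 for the consensus range and at 0.975 / 0.025 for the lower
# and upper confidence-limit ranges.

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Extract environmental values at occurrence points
#'
#' Looks up the layer values of the cell containing each record.  Points
#' falling outside the grid or on masked cells are dropped with a message
#' giving the count.
#'
#' @param stack an [env_stack()].
#' @param set an `occurrence_set`.
#' @return A data frame with one row per retained point and one column per
#'   layer, plus `row` and `col` cell indices.
#' @export
extract_features <- function(stack, set) {
  stopifnot(inherits(stack, "env_stack"), inherits(set, "occurrence_set"))
  if (nrow(set$records) == 0) stop("no records to extract")
  xy <- project_equal_area(set$records$lon, set$records$lat)
  rc <- grid_cell_of(stack$grid, xy[, 1], xy[, 2])
  on_grid <- !is.na(rc[, 1])
  valid <- on_grid
  valid[on_grid] <- stack$valid_mask[cbind(rc[on_grid, 1], rc[on_grid, 2])]
  dropped <- sum(!valid)
  if (dropped == nrow(rc))
    stop("all ", dropped, " point(s) fall outside the valid grid")
  if (dropped > 0)
    message(dropped, " point(s) outside the valid grid dropped")
  rc <- rc[valid, , drop = FALSE]
  out <- as.data.frame(lapply(stack$layers, function(l)
    l[cbind(rc[, 1], rc[, 2])]))
  out$row <- rc[, 1]
  out$col <- rc[, 2]
  out
}

#' Sample background cells uniformly without replacement
#'
#' @param stack an [env_stack()].
#' @param n number of background points; clipped to the number of valid
#'   cells with a warning if larger.
#' @param seed integer seed making the draw reproducible.
#' @return A data frame of layer values with `row`/`col`, as
#'   [extract_features()].
#' @export
sample_background <- function(stack, n, seed) {
  stopifnot(inherits(stack, "env_stack"), n >= 1)
  valid_cells <- which(stack$valid_mask, arr.ind = TRUE)
  nv <- nrow(valid_cells)
  if (n > nv) {
    warning("background n = ", n, " exceeds the ", nv,
            " valid cells; using all of them")
    n <- nv
  }
  idx <- .with_seed(seed, sample.int(nv, n))
  rc <- valid_cells[idx, , drop = FALSE]
  out <- as.data.frame(lapply(stack$layers, function(l)
    l[cbind(rc[, 1], rc[, 2])]))
  out$row <- rc[, 1]
  out$col <- rc[, 2]
  out
}

# Build the standardized design matrix for given raw layer values.
.design_matrix <- function(df, layer_names, feature_spec, std) {
  cols <- list()
  for (nm in layer_names) {
    z <- (df[[nm]] - std$mean[nm]) / std$sd[nm]
    if ("linear" %in% feature_spec[[nm]]) cols[[paste0(nm, "_l")]] <- z
    if ("quadratic" %in% feature_spec[[nm]]) cols[[paste0(nm, "_q")]] <- z^2
  }
  do.call(cbind, cols)
}

#' Fit a penalized presence-background suitability model
#'
#' Ridge-penalized logistic regression of presence (1) against background
#' (0) on standardized linear and quadratic terms of every layer (the full
#' variable set; no subset selection).  Fitted by iteratively reweighted
#' least squares; the intercept is unpenalized.  This is the package's
#' maximum-entropy surrogate: it fills the same pipeline role (a smooth
#' [0,1] suitability surface from presences and background) behind an
#' interface a different model could be slotted into.
#'
#' @param presence,background data frames of raw layer values (as returned
#'   by [extract_features()] / [sample_background()]); each needs at least
#'   two rows.
#' @param feature_spec character vector of feature classes applied to every
#'   layer, or a named list giving classes per layer; subset of
#'   `"linear"`, `"quadratic"`.
#' @param lambda nonnegative ridge penalty on the standardized coefficients
#'   (default 1.0).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An object of class `suitability_model` with elements
#'   `coefficients`, `standardization`, `feature_spec`, `layer_names`.
#' @export
fit_model <- function(presence, background,
                      feature_spec = c("linear", "quadratic"),
                      lambda = 1.0, max_iter = 100, tol = 1e-8) {
  layer_names <- setdiff(intersect(names(presence), names(background)),
                         c("row", "col"))
  if (length(layer_names) == 0) stop("no shared layer columns")
  if (nrow(presence) < 2 || nrow(background) < 2)
    stop("need at least 2 presence and 2 background rows")
  if (!is.list(feature_spec))
    feature_spec <- stats::setNames(
      rep(list(feature_spec), length(layer_names)), layer_names)
  all_rows <- rbind(presence[layer_names], background[layer_names])
  std <- list(mean = vapply(all_rows, mean, 0), sd = vapply(all_rows, stats::sd, 0))
  degenerate <- layer_names[std$sd[layer_names] == 0 |
                              !is.finite(std$sd[layer_names])]
  if (length(degenerate)) {
    warning("zero-variance layer(s) dropped: ",
            paste(degenerate, collapse = ", "))
    layer_names <- setdiff(layer_names, degenerate)
    if (length(layer_names) == 0) stop("all layers are degenerate")
  }
  X <- .design_matrix(all_rows, layer_names, feature_spec, std)
  y <- c(rep(1, nrow(presence)), rep(0, nrow(background)))
  p <- ncol(X)
  Xd <- cbind(`(Intercept)` = 1, X)
  pen <- diag(c(0, rep(lambda, p)), p + 1)   # intercept unpenalized
  beta <- rep(0, p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    # Newton step on the penalized log-likelihood
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("IRLS did not converge in ", max_iter, " iterations")
  structure(list(coefficients = stats::setNames(drop(beta), colnames(Xd)),
                 standardization = std, feature_spec = feature_spec,
                 layer_names = layer_names, lambda = lambda,
                 iterations = it),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("suitability_model: %d layer(s), lambda = %g, %d IRLS iteration(s)\n",
              length(x$layer_names), x$lambda, x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict a model over a data frame of layer values
#'
#' @param object a `suitability_model`.
#' @param newdata data frame with the model's layer columns.
#' @param ... unused.
#' @return Numeric vector of suitabilities in `[0, 1]`.
#' @export
predict.suitability_model <- function(object, newdata, ...) {
  if (!all(object$layer_names %in% names(newdata)))
    stop("newdata lacks layer(s): ",
         paste(setdiff(object$layer_names, names(newdata)), collapse = ", "))
  X <- .design_matrix(newdata, object$layer_names, object$feature_spec,
                      object$standardization)
  stats::plogis(drop(cbind(1, X) %*% object$coefficients))
}

#' Predict a suitability map over a stack
#'
#' @param model a `suitability_model` fitted on the stack's layer names.
#' @param stack an [env_stack()].
#' @return Numeric matrix of suitabilities in `[0,1]`; masked cells are
#'   `NA`.
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(model, "suitability_model"), inherits(stack, "env_stack"))
  if (!all(model$layer_names %in% names(stack$layers)))
    stop("stack lacks layer(s) the model was fitted on")
  df <- as.data.frame(lapply(stack$layers[model$layer_names], as.vector))
  s <- predict(model, df)
  m <- matrix(s, stack$grid$n_rows, stack$grid$n_cols)
  m[!stack$valid_mask] <- NA
  m
}

#' Area under the ROC curve by rank sum
#'
#' The Mann-Whitney probability that a random presence scores above a
#' random background point, with half credit for ties.
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4), c(0.5, 0.1))  # 0.75
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) stop("both score vectors must be nonempty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Binarization threshold maximizing sensitivity + specificity
#'
#' Youden's index over candidate thresholds taken from the observed scores,
#' counting a cell as predicted suitable when its score is at or above the
#' threshold.  Ties are broken toward the lowest threshold, which yields
#' the largest predicted range (the precautionary choice).
#'
#' @inheritParams auc
#' @return The selected threshold.
#' @export
select_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0 || length(background_scores) == 0)
    stop("both score vectors must be nonempty")
  cand <- sort(unique(c(presence_scores, background_scores)))
  youden <- vapply(cand, function(t)
    mean(presence_scores >= t) + mean(background_scores < t), 0)
  cand[which.max(youden)]   # which.max takes the first (lowest) maximizer
}

#' Displace records within their positional error radius
#'
#' Each record moves independently: direction uniform on `[0, 2*pi)`,
#' distance uniform on `[0, uncertainty_km]`, on the equal-area plane.
#' Records with `NA` uncertainty use `default_uncertainty_km`.
#'
#' @param set an `occurrence_set`.
#' @param seed integer seed.
#' @param default_uncertainty_km radius for records with no stated
#'   uncertainty.
#' @return A displaced `occurrence_set` (uncertainties preserved).
#' @export
jitter_records <- function(set, seed, default_uncertainty_km = 0) {
  stopifnot(inherits(set, "occurrence_set"))
  n <- nrow(set$records)
  if (n == 0) return(set)
  u <- set$records$uncertainty_km
  u[is.na(u)] <- default_uncertainty_km
  xy <- project_equal_area(set$records$lon, set$records$lat)
  d <- .with_seed(seed, {
    theta <- stats::runif(n, 0, 2 * pi)
    dist_m <- stats::runif(n, 0, u * 1000)
    cbind(dist_m * cos(theta), dist_m * sin(theta))
  })
  ll <- unproject_equal_area(xy[, 1] + d[, 1], xy[, 2] + d[, 2])
  out <- set
  out$records$lon <- ll[, 1]
  out$records$lat <- ll[, 2]
  out
}

#' Run the uncertainty-propagating model ensemble
#'
#' For each of `R` runs: jitter the records within their error radii, thin
#' to one presence per cell, draw a background sample, fit the suitability
#' model, predict the map, binarize at the Youden threshold, and score the
#' run by its training AUC.  Runs are combined with weights
#' `max(0, AUC - 0.5)^2` into the weighted vote-share map and its 50% /
#' 97.5% / 2.5% threshold maps.  Per-run seeds are `seed + run`, so any
#' single run can be replayed.
#'
#' @param set an `occurrence_set` (nonempty).
#' @param stack an [env_stack()].
#' @param R number of runs (default 100).
#' @param background_n background sample size per run; default
#'   `min(1000, valid cells)`.
#' @param lambda ridge penalty passed to [fit_model()].
#' @param seed integer master seed.
#' @param default_uncertainty_km positional error for records lacking one;
#'   default half the environmental cell edge.
#' @param feature_spec feature classes per layer, as [fit_model()].
#' @return An object of class `ensemble_result`: `runs` (data frame of
#'   `run`, `auc`, `weight`, `threshold`, `seed`), `binary_maps` (list of
#'   logical matrices), `score_map`, and [range_map()]s `consensus_map`,
#'   `lower_cl_map`, `upper_cl_map`.
#' @export
run_ensemble <- function(set, stack, R = 100, background_n = NULL,
                         lambda = 1.0, seed = 1,
                         default_uncertainty_km = NULL,
                         feature_spec = c("linear", "quadratic")) {
  stopifnot(inherits(set, "occurrence_set"), inherits(stack, "env_stack"),
            R >= 1)
  if (nrow(set$records) == 0) stop("empty occurrence set")
  nv <- sum(stack$valid_mask)
  if (is.null(background_n)) background_n <- min(1000, nv)
  if (is.null(default_uncertainty_km))
    default_uncertainty_km <- stack$grid$cell_m / 2000
  runs <- data.frame(run = seq_len(R), auc = NA_real_, weight = NA_real_,
                     threshold = NA_real_, seed = seed + seq_len(R))
  binary_maps <- vector("list", R)
  for (i in seq_len(R)) {
    run_seed <- seed + i
    jit <- jitter_records(set, seed = run_seed,
                          default_uncertainty_km = default_uncertainty_km)
    thin <- thin_to_cells(jit, stack$grid)
    pres <- tryCatch(suppressMessages(extract_features(stack, thin)),
                     error = function(e) NULL)
    if (is.null(pres) || nrow(pres) < 2) {
      # jitter pushed (almost) everything off the valid grid: fall back to
      # the unjittered records for this run
      thin <- thin_to_cells(set, stack$grid)
      pres <- suppressMessages(extract_features(stack, thin))
      if (nrow(pres) < 2)
        stop("fewer than 2 records fall on the valid grid")
    }
    bg <- suppressWarnings(
      sample_background(stack, background_n, seed = run_seed))
    model <- fit_model(pres, bg, feature_spec = feature_spec, lambda = lambda)
    smap <- predict_map(model, stack)
    p_scores <- predict(model, pres)
    b_scores <- predict(model, bg)
    a <- auc(p_scores, b_scores)
    thr <- select_threshold(p_scores, b_scores)
    runs$auc[i] <- a
    runs$weight[i] <- max(0, a - 0.5)^2
    runs$threshold[i] <- thr
    b <- smap >= thr
    b[is.na(b)] <- FALSE
    binary_maps[[i]] <- b
  }
  wsum <- sum(runs$weight)
  if (wsum <= 0)
    stop("uninformative ensemble: every run had AUC <= 0.5")
  score <- Reduce(`+`, Map(function(b, w) w * b, binary_maps, runs$weight)) /
    wsum
  score[!stack$valid_mask] <- NA
  as_map <- function(cut) {
    s <- score >= cut
    s[is.na(s)] <- FALSE
    range_map(stack$grid, s)
  }
  structure(list(runs = runs, binary_maps = binary_maps, score_map = score,
                 consensus_map = as_map(0.5),
                 lower_cl_map = as_map(0.975),
                 upper_cl_map = as_map(0.025),
                 grid = stack$grid,
                 parameters = list(R = R, background_n = background_n,
                                   lambda = lambda, seed = seed,
                                   default_uncertainty_km =
                                     default_uncertainty_km)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(paste0("ensemble_result: %d runs, mean AUC %.3f, consensus ",
                     "%d cells, lower CL %d cells\n"),
              nrow(x$runs), mean(x$runs$auc), sum(x$consensus_map$suitable),
              sum(x$lower_cl_map$suitable)))
  invisible(x)
}

#' Range metrics from an ensemble's consensus and lower-CL maps
#'
#' Optionally restricts each map to habitat patches containing observation
#' points (see [restrict_to_occupied_patches()]), then computes EOO and AOO
#' per map.  Assessments use the lower confidence limit under the
#' precautionary principle; both bounds are returned.
#'
#' @param ensemble an `ensemble_result`.
#' @param set the observed (unjittered) `occurrence_set`; required when
#'   `apply_habitat_filter` is TRUE.
#' @param apply_habitat_filter keep only patches containing records
#'   (default TRUE).
#' @param connectivity patch adjacency, 4 or 8 (default 8).
#' @return A list with `lower_cl` and `consensus` [range_metrics()].
#' @export
range_metrics_from_ensemble <- function(ensemble, set = NULL,
                                        apply_habitat_filter = TRUE,
                                        connectivity = 8) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  one <- function(map, bound) {
    if (apply_habitat_filter) {
      if (is.null(set)) stop("habitat filter requires the occurrence set")
      map <- restrict_to_occupied_patches(map, set,
                                          connectivity = connectivity)
    }
    if (!any(map$suitable)) {
      warning("empty ", bound, " map after restriction; metrics set to 0")
      return(range_metrics(0, 0, basis = "sdm", bound = bound))
    }
    range_metrics(eoo_from_map(map), aoo_from_map(map),
                  basis = "sdm", bound = bound)
  }
  list(lower_cl = one(ensemble$lower_cl_map, "lower_cl"),
       consensus = one(ensemble$consensus_map, "consensus"))
}

#' Serialize an ensemble run report to JSON
#'
#' Per-run AUC/weight/threshold/seed plus the ensemble parameters, for
#' provenance alongside exported maps.
#'
#' @param ensemble an `ensemble_result`.
#' @param file optional path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
ensemble_report_json <- function(ensemble, file = NULL) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  obj <- list(parameters = ensemble$parameters,
              runs = ensemble$runs,
              consensus_cells = sum(ensemble$consensus_map$suitable),
              lower_cl_cells = sum(ensemble$lower_cl_map$suitable),
              upper_cl_cells = sum(ensemble$upper_cl_map$suitable))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                         dataframe = "rows")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
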