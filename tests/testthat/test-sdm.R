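test_that("AUC is the tie-aware rank-sum probability", {
  # brute force over the four pairs: 3 wins, 1 loss -> 0.75
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_equal(auc(0.1, 0.9), 0)
  expect_error(auc(numeric(0), 1), "nonempty")
  # random case against explicit pair enumeration
  set.seed(1)
  p <- round(runif(7), 2); b <- round(runif(9), 2)
  pairs <- outer(p, b, function(x, y) (x > y) + 0.5 * (x == y))
  expect_equal(auc(p, b), mean(pairs))
})

test_that("threshold selection maximizes Youden, ties to the lowest", {
  # enumerated case: 0.4 and 0.9 tie at sens+spec = 1.5; lower wins
  expect_equal(select_threshold(c(0.9, 0.4), c(0.5, 0.1)), 0.4)
  # perfect separation: the lowest presence score
  expect_equal(select_threshold(c(0.7, 0.8), c(0.1, 0.2)), 0.7)
  # identical distributions: every candidate ties, lowest observed wins
  expect_equal(select_threshold(c(0.3, 0.6), c(0.3, 0.6)), 0.3)
})

test_that("jitter respects the error radius and its mean displacement", {
  set <- pts_set(c(-8.5, -8.6), c(37.1, 37.2), u = 0)
  expect_equal(jitter_records(set, seed = 1)$records[, c("lon", "lat")],
               set$records[, c("lon", "lat")])
  # support bound: every displacement <= u
  big <- random_set(200, seed = 4)
  big$records$uncertainty_km <- 2
  jit <- jitter_records(big, seed = 2)
  d_km <- sqrt(rowSums((project_equal_area(jit$records$lon, jit$records$lat) -
                          project_equal_area(big$records$lon,
                                             big$records$lat))^2)) / 1000
  expect_true(all(d_km <= 2 + 1e-9))
  # E(d) = u/2 for distance uniform on [0, u]
  one <- pts_set(rep(0, 10000), rep(0, 10000), u = 2)
  jd <- jitter_records(one, seed = 3)
  xy <- project_equal_area(jd$records$lon, jd$records$lat)
  expect_equal(mean(sqrt(rowSums(xy^2)) / 1000), 1.0, tolerance = 0.05)
  # reproducibility and NA resolution via the default radius
  expect_identical(jitter_records(big, seed = 9)$records,
                   jitter_records(big, seed = 9)$records)
})

test_that("background sampling is uniform, exhaustive and reproducible", {
  w <- small_world(seed = 11, n = 12)
  nv <- sum(w$stack$valid_mask)
  all_cells <- sample_background(w$stack, nv, seed = 1)
  expect_equal(nrow(all_cells), nv)
  expect_equal(anyDuplicated(all_cells[c("row", "col")]), 0)
  expect_warning(over <- sample_background(w$stack, nv + 50, seed = 1),
                 "exceeds")
  expect_equal(nrow(over), nv)
  expect_identical(sample_background(w$stack, 30, seed = 5),
                   sample_background(w$stack, 30, seed = 5))
  # inclusion frequencies uniform within binomial error: chi-square over
  # repeated seeds
  counts <- integer(nv)
  draws <- 400
  for (s in 1:draws) {
    idx <- sample_background(w$stack, 20, seed = 10000 + s)
    counts[(idx$col - 1) * w$stack$grid$n_rows + idx$row] <-
      counts[(idx$col - 1) * w$stack$grid$n_rows + idx$row] + 1L
  }
  expected <- draws * 20 / nv
  chisq <- sum((counts - expected)^2 / expected)
  # df = nv - 1; generous upper quantile
  expect_lt(chisq, qchisq(0.999, nv - 1))
})

test_that("feature extraction drops masked and off-grid points", {
  w <- small_world(seed = 21, n = 10)
  g <- w$stack$grid
  ctr <- rangeprofile:::grid_cell_centre(g, 4, 7)
  ll <- unproject_equal_area(ctr[, 1], ctr[, 2])
  row_vals <- extract_features(w$stack, pts_set(ll[, 1], ll[, 2]))
  expect_equal(row_vals$env1, w$stack$layers$env1[4, 7])
  expect_equal(row_vals$env2, w$stack$layers$env2[4, 7])

  # five points, one on a masked cell -> four rows
  mask <- w$stack$valid_mask; mask[4, 7] <- FALSE
  masked <- env_stack(g, w$stack$layers, mask)
  five <- rangeprofile:::grid_cell_centre(g, c(1, 2, 3, 4, 5), c(1, 3, 5, 7, 9))
  ll5 <- unproject_equal_area(five[, 1], five[, 2])
  expect_message(rows <- extract_features(masked, pts_set(ll5[, 1], ll5[, 2])),
                 "dropped")
  expect_equal(nrow(rows), 4)
  # point far outside the grid
  expect_message(out <- extract_features(w$stack, pts_set(c(ll[, 1], 50),
                                                          c(ll[, 2], 50))),
                 "dropped")
  expect_equal(nrow(out), 1)
  expect_error(extract_features(w$stack, pts_set(50, 50)), "outside")
})

test_that("model fitting separates, shrinks, and flags degeneracy", {
  # one perfectly separating layer
  pres <- data.frame(env1 = c(2, 2.5, 3, 3.5))
  bg <- data.frame(env1 = c(-2, -2.5, -3, -3.5))
  m <- fit_model(pres, bg, feature_spec = "linear", lambda = 0.5)
  expect_true(min(predict(m, pres)) > max(predict(m, bg)))
  # heavy penalty: predictions collapse to the prevalence
  m_inf <- fit_model(pres, bg, feature_spec = "linear", lambda = 1e8)
  expect_equal(unname(predict(m_inf, data.frame(env1 = c(-3, 0, 3)))),
               rep(0.5, 3), tolerance = 1e-3)
  # zero-variance layer dropped with a warning
  pres2 <- cbind(pres, env2 = 1); bg2 <- cbind(bg, env2 = 1)
  expect_warning(m2 <- fit_model(pres2, bg2, lambda = 0.5), "zero-variance")
  expect_false("env2" %in% m2$layer_names)
  expect_error(fit_model(pres[1, , drop = FALSE], bg), "at least 2")
})

test_that("shuffled labels give chance-level training AUC", {
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(200)
    lab <- sample(rep(c(TRUE, FALSE), 100))
    m <- fit_model(data.frame(env1 = x[lab]), data.frame(env1 = x[!lab]))
    auc(predict(m, data.frame(env1 = x[lab])),
        predict(m, data.frame(env1 = x[!lab])))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("ridge logistic fit matches glmnet on a fixed design", {
  set.seed(8)
  pres <- data.frame(a = rnorm(40, 1), b = rnorm(40, -0.5))
  bg <- data.frame(a = rnorm(120), b = rnorm(120))
  lam <- 2.0
  m <- fit_model(pres, bg, lambda = lam)
  # independent route: explicit standardized design, glmnet ridge with the
  # equivalent per-observation penalty (glmnet scales the loss by 1/n)
  all_rows <- rbind(pres, bg)
  z <- scale(all_rows)
  X <- cbind(a_l = z[, 1], a_q = z[, 1]^2, b_l = z[, 2], b_q = z[, 2]^2)
  y <- rep(1:0, c(40, 120))
  n <- length(y)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = lam / n, standardize = FALSE,
                      thresh = 1e-12, maxit = 1e6)
  got <- unname(m$coefficients)
  want <- unname(as.numeric(coef(g)))
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("map prediction is monotone and matches the closed form", {
  g <- grid_spec(0, 0, 1000, 6, 6)
  mono <- matrix(rep(seq(-2, 2, length.out = 6), each = 6), 6, 6)
  stack <- env_stack(g, list(env1 = mono))
  set.seed(2)
  pres <- data.frame(env1 = rnorm(10, 1.5, 0.3))
  bg <- data.frame(env1 = rnorm(50, 0, 1))
  m <- fit_model(pres, bg, feature_spec = "linear")
  smap <- predict_map(m, stack)
  expect_true(all(smap >= 0 & smap <= 1))
  expect_true(all(diff(smap[1, ]) > 0))  # monotone along the gradient
  # closed-form evaluation on three cells
  for (cell in list(c(1, 1), c(3, 4), c(6, 6))) {
    zv <- (mono[cell[1], cell[2]] - m$standardization$mean["env1"]) /
      m$standardization$sd["env1"]
    eta <- m$coefficients[1] + m$coefficients["env1_l"] * zv
    expect_equal(smap[cell[1], cell[2]], unname(plogis(eta)))
  }
  # constant stack -> constant map; layer-name mismatch errors
  const <- env_stack(g, list(env1 = matrix(0.7, 6, 6)))
  expect_equal(length(unique(as.vector(predict_map(m, const)))), 1)
  expect_error(predict_map(m, env_stack(g, list(other = mono))), "lacks")
})

test_that("ensemble runs are weighted, nested, and seed-reproducible", {
  w <- small_world(seed = 31, n = 25, n_presences = 10)
  ens <- run_ensemble(w$set, w$stack, R = 12, background_n = 120, seed = 5)
  # weight law applied run by run
  expect_equal(ens$runs$weight, pmax(0, ens$runs$auc - 0.5)^2)
  # score map equals the weight-normalized vote recomputed independently
  score2 <- Reduce(`+`, Map(function(b, wt) wt * b,
                            ens$binary_maps, ens$runs$weight)) /
    sum(ens$runs$weight)
  expect_equal(ens$score_map[w$stack$valid_mask],
               score2[w$stack$valid_mask])
  # threshold nesting
  expect_true(all(ens$lower_cl_map$suitable <= ens$consensus_map$suitable))
  expect_true(all(ens$consensus_map$suitable <= ens$upper_cl_map$suitable))
  # bitwise determinism
  ens2 <- run_ensemble(w$set, w$stack, R = 12, background_n = 120, seed = 5)
  expect_identical(ens$score_map, ens2$score_map)
  expect_identical(ens$runs, ens2$runs)
})

test_that("hand-weighted vote: weights (0.1,0.2,0.3), suitable in runs 2+3", {
  # the score of a cell suitable in runs 2 and 3 only is (0.2+0.3)/0.6
  b1 <- matrix(FALSE, 1, 1); b2 <- matrix(TRUE, 1, 1); b3 <- matrix(TRUE, 1, 1)
  wts <- c(0.1, 0.2, 0.3)
  score <- Reduce(`+`, Map(`*`, list(b1, b2, b3), wts)) / sum(wts)
  expect_equal(score[1, 1], 0.8333333, tolerance = 1e-6)
  expect_true(score[1, 1] >= 0.5)    # in the consensus map
  expect_false(score[1, 1] >= 0.975) # not in the lower confidence limit
})

test_that("ensemble range metrics order lower CL below consensus", {
  w <- small_world(seed = 41, n = 25, n_presences = 10)
  ens <- run_ensemble(w$set, w$stack, R = 20, background_n = 120, seed = 7)
  m <- range_metrics_from_ensemble(ens, w$set)
  expect_lte(m$lower_cl$eoo_km2, m$consensus$eoo_km2)
  expect_lte(m$lower_cl$aoo_km2, m$consensus$aoo_km2)
  expect_equal(m$lower_cl$basis, "sdm")
  expect_equal(m$lower_cl$bound, "lower_cl")
  # unfiltered variant needs no records and still nests
  m2 <- range_metrics_from_ensemble(ens, apply_habitat_filter = FALSE)
  expect_lte(m2$lower_cl$aoo_km2, m2$consensus$aoo_km2)
  # report serializes with per-run provenance
  js <- jsonlite::fromJSON(ensemble_report_json(ens))
  expect_equal(nrow(js$runs), 20)
  expect_equal(js$parameters$seed, 7)
})
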