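test_that("landscapes are standardized, smoothed, and seed-pure", {
  cfg <- simulation_config(seed = 5, n_rows = 40, n_cols = 40,
                           smooth_sigma_cells = 5)
  stack <- make_landscape(cfg)
  for (l in stack$layers) {
    expect_equal(mean(l), 0, tolerance = 1e-12)
    expect_equal(sd(l), 1, tolerance = 1e-12)
  }
  # same seed, same stack; different seed differs
  expect_identical(make_landscape(cfg)$layers, stack$layers)
  cfg2 <- cfg; cfg2$seed <- 6
  expect_false(identical(make_landscape(cfg2)$layers, stack$layers))

  # smoothing induces spatial autocorrelation; raw noise has none
  lag1 <- function(m) cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  rough <- simulation_config(seed = 5, n_rows = 40, n_cols = 40,
                             smooth_sigma_cells = 0)
  ac_rough <- mean(vapply(1:10, function(s) {
    c2 <- rough; c2$seed <- s
    lag1(make_landscape(c2)$layers[[1]])
  }, 0))
  ac_smooth <- mean(vapply(1:10, function(s) {
    c2 <- cfg; c2$seed <- s
    lag1(make_landscape(c2)$layers[[1]])
  }, 0))
  expect_lt(abs(ac_rough), 0.1)
  expect_gt(ac_smooth, 0.5)
})

test_that("virtual species follow the logistic closed form", {
  cfg <- simulation_config(seed = 9, n_rows = 15, n_cols = 15)
  stack <- make_landscape(cfg)
  expect_error(make_virtual_species(stack, c(0, 1)), "coefficients")
  # all-zero coefficients: suitability one half everywhere, range = all
  flat <- make_virtual_species(stack, c(0, 0, 0, 0))
  expect_true(all(flat$true_suitability == 0.5))
  expect_true(all(flat$true_range$suitable))
  # hand-evaluated cell
  vs <- make_virtual_species(stack, c(0.3, 2, -1, 0.5), cut = 0.6)
  eta <- 0.3 + 2 * stack$layers$env1[4, 9] - stack$layers$env2[4, 9] +
    0.5 * stack$layers$env3[4, 9]
  expect_equal(vs$true_suitability[4, 9], plogis(eta))
  expect_equal(vs$true_range$suitable[4, 9], plogis(eta) >= 0.6)
  # a monotone layer yields monotone suitability in that layer
  g <- grid_spec(0, 0, 1000, 5, 5)
  mono <- matrix(rep(seq(-2, 2, length.out = 5), each = 5), 5, 5)
  vmono <- make_virtual_species(env_stack(g, list(env1 = mono)), c(0, 1.5))
  expect_true(all(diff(vmono$true_suitability[1, ]) > 0))
})

test_that("presence sampling is suitability-proportional and seeded", {
  g <- grid_spec(0, 0, 1000, 4, 4)
  onehot <- matrix(1e-12, 4, 4); onehot[2, 3] <- 1
  vs <- list(true_suitability = onehot,
             true_range = range_map(g, onehot > 0.5))
  class(vs) <- "virtual_species"
  one <- sample_presences(vs, 1, uncertainty_km = 0, seed = 1)
  xy <- project_equal_area(one$records$lon, one$records$lat)
  rc <- rangeprofile:::grid_cell_of(g, xy[, 1], xy[, 2])
  expect_equal(unname(rc[1, ]), c(2, 3))

  # empirical draw frequencies proportional to suitability (chi-square)
  cfg <- simulation_config(seed = 2, n_rows = 8, n_cols = 8)
  stack <- make_landscape(cfg)
  vsr <- make_virtual_species(stack, cfg$true_coefficients)
  n <- 10000
  draws <- sample_presences(vsr, n, uncertainty_km = 0, seed = 3)
  xy <- project_equal_area(draws$records$lon, draws$records$lat)
  rc <- rangeprofile:::grid_cell_of(stack$grid, xy[, 1], xy[, 2])
  counts <- table(factor(paste(rc[, 1], rc[, 2]),
                         levels = as.vector(outer(1:8, 1:8, paste))))
  p <- as.vector(vsr$true_suitability) / sum(vsr$true_suitability)
  chisq <- sum((as.integer(counts) - n * p)^2 / (n * p))
  expect_lt(chisq, qchisq(0.999, 63))
  expect_identical(sample_presences(vsr, 5, 1, seed = 4)$records,
                   sample_presences(vsr, 5, 1, seed = 4)$records)
  expect_equal(draws$records$uncertainty_km, rep(0, n))
})

test_that("cave clusters obey their spread and range bounds", {
  # zero spread: identical points, degenerate EOO, a single 2-km cell
  tight <- make_cave_points(4, -8.6, 37.1, spread_km = 0, seed = 1)
  expect_equal(n_records(tight), 4)
  expect_equal(length(unique(tight$records$lon)), 1)
  expect_equal(eoo_from_points(tight), 0)
  expect_equal(aoo_from_points(tight), 4)
  # AOO bounded by 4k
  spread <- make_cave_points(4, -8.6, 37.1, spread_km = 10, seed = 2)
  expect_lte(aoo_from_points(spread), 16)
  # Monte Carlo: per-axis displacement sd matches spread
  big <- make_cave_points(10000, 0, 0, spread_km = 3, seed = 3)
  xy <- project_equal_area(big$records$lon, big$records$lat)
  expect_equal(sd(xy[, 1]) / 1000, 3, tolerance = 0.1)
  expect_equal(sd(xy[, 2]) / 1000, 3, tolerance = 0.1)
})
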