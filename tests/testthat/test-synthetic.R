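test_that("generators are pure functions of seed", {
  g <- ll_grid(25, 25)
  e1 <- make_national_environment(g, seed = 5)
  e2 <- make_national_environment(g, seed = 5)
  for (nm in names(e1)) expect_identical(e1[[nm]]$values, e2[[nm]]$values)
  expect_false(identical(make_national_environment(g, seed = 6)$bio9$values,
                         e1$bio9$values))

  p1 <- make_provincial_environment(ea_grid(25), seed = 3)
  p2 <- make_provincial_environment(ea_grid(25), seed = 3)
  expect_identical(p1$elevation$values, p2$elevation$values)
  expect_identical(p1$dist_water$values, p2$dist_water$values)

  s <- true_suitability(e1, truth_model())
  expect_identical(sample_occurrences(s, 40, seed = 9),
                   sample_occurrences(s, 40, seed = 9))
})

test_that("national fields respect gradient and ranges", {
  g <- ll_grid(30, 25)
  env <- make_national_environment(g, seed = 2)
  grad <- bio9_gradient(g)
  # row means of the noise-free gradient decrease strictly from the
  # southern (last) row towards the northern (first) row
  expect_true(all(diff(rowMeans(grad)) > 0))
  expect_lt(rowMeans(grad)[1], rowMeans(grad)[30])
  expect_equal(max(grad), 20)
  expect_equal(min(grad), -15)
  expect_true(all(env$bio14$values >= 0 & env$bio14$values <= 100))
  expect_true(all(env$lulc$values %in% 1:6))
  expect_true(min(env$bio9$values) > -25 && max(env$bio9$values) < 30)
  expect_error(make_national_environment(ll_grid(10, 10)), "too small")
})

test_that("truth suitability has the declared marginal structure", {
  g <- ll_grid(25, 25)
  env <- make_national_environment(g, seed = 8)
  # all-zero coefficients: constant 0.5 map
  flat <- truth_model(intercept = 0, bio9_curvature = 1e-9,
                      coefficients = list())
  flat$coefficients$bio9 <- c(0, 0)
  expect_equal(unique(as.vector(true_suitability(env, flat)$values)), 0.5)

  # brute-force argmax of the bio9 marginal equals the declared optimum
  tru <- truth_model(optimum_bio9 = 2.5)
  bio9_seq <- seq(-15, 20, by = 0.01)
  eta <- tru$intercept + tru$coefficients$bio9[1] * bio9_seq +
    tru$coefficients$bio9[2] * bio9_seq^2
  expect_lt(abs(bio9_seq[which.max(plogis(eta))] - 2.5), 0.011)

  expect_error(true_suitability(env["lulc"], truth_model()),
               "missing predictor")
})

test_that("occurrence sampling follows the suitability weights", {
  g <- ea_grid(10)
  v <- matrix(0, 10, 10); v[4, 7] <- 1
  one <- make_raster(g, v)
  pt <- sample_occurrences(one, 1, seed = 1)
  expect_equal(pt$x, cell_centers_x(g)[7])
  expect_equal(pt$y, cell_centers_y(g)[4])
  expect_error(sample_occurrences(one, 2, seed = 1), "positive suitability")

  # uniform suitability: cell frequencies uniform over repeated draws
  unif <- make_raster(g, matrix(1, 10, 10))
  counts <- integer(100)
  for (s in 1:150) {
    occ <- sample_occurrences(unif, 40, seed = s)
    rc <- point_to_cell(g, occ$x, occ$y)
    idx <- (rc$col - 1) * 10 + rc$row
    counts[idx] <- counts[idx] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("provincial stack geometry is self-consistent", {
  g <- ea_grid(30, 300)
  env <- make_provincial_environment(g, seed = 11)
  river <- attr(env, "river_cells")
  expect_true(all(env$dist_water$values[river] == 0))
  # independent re-computation of the distance for a probe cell
  cx <- cell_centers_x(g); cy <- cell_centers_y(g)
  probe <- c(15, 3)
  d_hand <- min(sqrt((cx[probe[2]] - cx[river[, 2]])^2 +
                     (cy[probe[1]] - cy[river[, 1]])^2))
  expect_equal(env$dist_water$values[probe[1], probe[2]], d_hand)
  # a lateral neighbour of a river cell on a straight stretch is exactly
  # one cell away from the water
  col <- river[, 2]
  straight <- which(col[-c(1, 2)] == col[-c(1, nrow(river))] &
                    col[-c(nrow(river) - 1, nrow(river))] == col[-c(1, nrow(river))]) + 1
  straight <- straight[col[straight] < 30 - 1 & col[straight] > 2]
  if (length(straight)) {
    i <- straight[1]
    expect_equal(min(env$dist_water$values[i, col[i] + 1],
                     env$dist_water$values[i, col[i] - 1]), 300)
  }
  expect_true(all(env$slope$values >= 0))
  expect_true(all(env$lulc$values[river] == 4))   # wetland corridor
})

test_that("slope and aspect derive from elevation by finite differences", {
  flat <- hsdm:::terrain_slope_aspect(matrix(700, 8, 8), 300)
  expect_true(all(flat$slope == 0))
  # a plane dipping 1 m per cell eastward: slope atan(1/300) everywhere
  plane <- matrix(rep(8:1, each = 8), 8, 8)
  tr <- hsdm:::terrain_slope_aspect(plane, 300)
  expect_equal(unique(as.vector(tr$slope[, 2:7])),
               atan(1 / 300) * 180 / pi)
})

test_that("known-rule land-cover series converts exactly the rule cells", {
  g <- ea_grid(40, 300)
  frozen <- make_lulc_series(g, seed = 5, growth_distance = 0)
  expect_identical(frozen$lulc_t0$values, frozen$lulc_t1$values)
  expect_identical(frozen$lulc_t1$values, frozen$lulc_t2$values)

  ser <- make_lulc_series(g, seed = 5, growth_distance = 1500)
  n_imp <- vapply(list(ser$lulc_t0, ser$lulc_t1, ser$lulc_t2),
                  function(m) sum(m$values == 5), 0)
  expect_true(all(diff(n_imp) >= 0))
  # converted cells are exactly those satisfying the distance rule
  du <- ser$drivers$dist_urban$values
  expected_t1 <- ser$lulc_t0$values
  expected_t1[expected_t1 == 3 & du <= ser$rule$d1] <- 5
  expect_identical(ser$lulc_t1$values, expected_t1)
  expected_t2 <- ser$lulc_t1$values
  expected_t2[expected_t2 == 3 & du <= ser$rule$d2] <- 5
  expect_identical(ser$lulc_t2$values, expected_t2)
})

test_that("climate scenarios shift the stack as declared", {
  g <- ll_grid(25, 25)
  env <- make_national_environment(g, seed = 4)
  none <- make_future_climate(env, scenario_spec("SSP126", "2030s",
                                                 temperature_delta = 0,
                                                 precipitation_factor = 1))
  expect_identical(none$bio9$values, env$bio9$values)
  expect_identical(none$bio14$values, env$bio14$values)

  warm <- make_future_climate(env, scenario_spec("SSP585", "2030s"))
  expect_equal(mean(warm$bio9$values) - mean(env$bio9$values), 1.5)
  expect_identical(warm$lulc$values, env$lulc$values)

  # scenario ordering invariant: deltas SSP126 <= SSP245 <= SSP585
  for (per in c("2030s", "2050s")) {
    d <- vapply(c("SSP126", "SSP245", "SSP585"),
                function(s) scenario_spec(s, per)$temperature_delta, 0)
    expect_true(all(diff(d) >= 0))
  }
})

test_that("protected-area blobs cover the requested fraction", {
  g <- ea_grid(100)
  expect_equal(sum(make_protected_areas(g, 0, seed = 1)$values), 0)
  expect_equal(sum(make_protected_areas(g, 1, seed = 1)$values), 10000)
  cov <- mean(make_protected_areas(g, 0.1, seed = 2)$values)
  expect_gte(cov, 0.09); expect_lte(cov, 0.11)
})
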