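test_that("demand extrapolates linearly and conserves the total", {
  g <- ea_grid(20, 300)
  # class A: 100 -> 110 cells over 10 y; class B compensates; C..F stable
  m1 <- matrix(rep(c(1, 2, 3, 4, 5, 6), c(100, 110, 50, 50, 45, 45)), 20, 20)
  m2 <- matrix(rep(c(1, 2, 3, 4, 5, 6), c(110, 100, 50, 50, 45, 45)), 20, 20)
  r1 <- make_raster(g, m1, kind = "categorical")
  r2 <- make_raster(g, m2, kind = "categorical")
  same <- estimate_demand(r1, r1, 10, 10)
  expect_equal(as.numeric(same), c(100, 110, 50, 50, 45, 45))
  d <- estimate_demand(r1, r2, 10, 10)
  expect_equal(d[["cropland"]], 120)   # 110 + (110-100) * 10/10
  expect_equal(d[["forest"]], 90)
  expect_equal(sum(d), 400)
  # clamping: a class headed below zero stops at zero and the vector is
  # rescaled to the cell total
  m3 <- matrix(rep(c(1, 2, 3, 4, 5, 6), c(205, 5, 50, 50, 45, 45)), 20, 20)
  d3 <- estimate_demand(r2, make_raster(g, m3, kind = "categorical"), 10, 30)
  expect_true(all(d3 >= 0))
  expect_equal(sum(d3), 400)
})

test_that("transition model learns a distance rule and fails on shuffled drivers", {
  g <- ea_grid(60, 300)
  ser <- make_lulc_series(g, seed = 3)
  drv <- list(dist_urban = ser$drivers$dist_urban)
  tr <- suppressWarnings(fit_transition_model(ser$lulc_t0, ser$lulc_t1, drv,
                                              seed = 5))
  expect_identical(
    suppressWarnings(fit_transition_model(ser$lulc_t0, ser$lulc_t1, drv,
                                          seed = 5))$impervious$values,
    tr$impervious$values)
  # the surface carries out-of-bag probabilities at its own training
  # cells, so ranking expansion cells against undisturbed grassland is an
  # honest held-out measure of how well the rule was learned
  expand1 <- ser$lulc_t0$values != 5 & ser$lulc_t1$values == 5
  none <- ser$lulc_t2$values != 5 & ser$lulc_t0$values == 3
  p <- tr$impervious$values
  obs <- c(rep(1, sum(expand1)), rep(0, sum(none)))
  expect_gte(auc(obs, c(p[expand1], p[none])), 0.95)

  # permutation control: shuffling the driver destroys the signal
  set.seed(6)
  shuffled <- drv
  shuffled$dist_urban$values[] <- sample(shuffled$dist_urban$values)
  tr0 <- suppressWarnings(fit_transition_model(ser$lulc_t0, ser$lulc_t1,
                                               shuffled, seed = 5))
  p0 <- tr0$impervious$values
  a0 <- auc(obs, c(p0[expand1], p0[none]))
  expect_gte(a0, 0.35); expect_lte(a0, 0.65)
})

test_that("classes without expansion cells get a zero surface with warning", {
  g <- ea_grid(25, 300)
  ser <- make_lulc_series(g, seed = 4, growth_distance = 1200)
  w <- capture_warnings(
    tr <- fit_transition_model(ser$lulc_t0, ser$lulc_t1,
                               list(dist_urban = ser$drivers$dist_urban),
                               seed = 2))
  expect_true(any(grepl("no expansion", w)))
  expect_true(all(tr$wetland$values == 0))
})

test_that("the CA meets demand, conserves cells and respects infeasibility", {
  g <- ea_grid(50, 300)
  ser <- make_lulc_series(g, seed = 9)
  drv <- list(dist_urban = ser$drivers$dist_urban)
  tr <- suppressWarnings(fit_transition_model(ser$lulc_t0, ser$lulc_t1, drv, seed = 1))

  cur <- vapply(1:6, function(k) sum(ser$lulc_t1$values == k), 0)
  names(cur) <- names(hsdm:::LULC_CLASSES)
  same <- simulate_lulc(ser$lulc_t1, tr, cur, seed = 2)
  expect_identical(same$values, ser$lulc_t1$values)

  dem <- estimate_demand(ser$lulc_t0, ser$lulc_t1, 10, 20)
  sim <- simulate_lulc(ser$lulc_t1, tr, dem, seed = 2)
  got <- vapply(1:6, function(k) sum(sim$values == k), 0)
  expect_equal(sum(got), 2500)                      # cells conserved
  expect_true(all(abs(got - dem) <= ceiling(0.01 * 2500)))
  expect_identical(simulate_lulc(ser$lulc_t1, tr, dem, seed = 2)$values,
                   sim$values)

  expect_error(simulate_lulc(ser$lulc_t1, tr, dem + 100, seed = 2),
               "infeasible")
})

test_that("with full neighbourhood weight and no seeding, growth stays attached", {
  g <- ea_grid(40, 300)
  ser <- make_lulc_series(g, seed = 12)
  tr <- suppressWarnings(fit_transition_model(
    ser$lulc_t0, ser$lulc_t1, list(dist_urban = ser$drivers$dist_urban), seed = 3))
  dem <- estimate_demand(ser$lulc_t0, ser$lulc_t1, 10, 30)
  sim <- simulate_lulc(ser$lulc_t1, tr, dem,
                       params = list(neighborhood_weight = 1, seed_prob = 0),
                       seed = 4)
  # flood-fill from the original impervious cells over the final mask:
  # every impervious cell must be reachable (no detached new patches)
  final <- sim$values == 5
  reached <- ser$lulc_t1$values == 5
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-nrow(reached), ]
    grown[-nrow(reached), ] <- grown[-nrow(reached), ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -ncol(reached)]
    grown[, -ncol(reached)] <- grown[, -ncol(reached)] | reached[, -1]
    # diagonals (Moore adjacency)
    grown[-1, -1] <- grown[-1, -1] | reached[-nrow(reached), -ncol(reached)]
    grown[-1, -ncol(reached)] <- grown[-1, -ncol(reached)] | reached[-nrow(reached), -1]
    grown[-nrow(reached), -1] <- grown[-nrow(reached), -1] | reached[-1, -ncol(reached)]
    grown[-nrow(reached), -ncol(reached)] <- grown[-nrow(reached), -ncol(reached)] | reached[-1, -1]
    grown <- grown & final | (ser$lulc_t1$values == 5)
    if (identical(grown, reached)) break
    reached <- grown
  }
  expect_true(all(reached[final]))
})

test_that("map agreement reproduces hand-computed OA and Kappa", {
  g <- ea_grid(10, 300)
  a <- make_raster(g, matrix(rep(1:2, each = 50), 10, 10), kind = "categorical")
  expect_equal(map_agreement(a, a)$overall_accuracy, 1)
  expect_equal(map_agreement(a, a)$kappa, 1)

  b <- a; b$values <- a$values + 2
  expect_equal(map_agreement(a, b)$overall_accuracy, 0)

  # confusion (40,10 / 10,40)
  s <- make_raster(g, matrix(rep(c(1, 2, 1, 2), c(40, 10, 10, 40)), 10, 10),
                   kind = "categorical")
  t <- make_raster(g, matrix(rep(c(1, 2), each = 50), 10, 10),
                   kind = "categorical")
  rep <- map_agreement(s, t)
  expect_equal(rep$overall_accuracy, 0.8)
  expect_equal(rep$kappa, 0.6)
})
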