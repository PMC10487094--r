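# Synthetic two-scale study system: smooth climate fields with a
# south-north temperature gradient, occurrences drawn from a known logistic
# suitability truth, distance-to-water decay, categorical land cover with
# known transition rules, scenario warming deltas, protected-area blobs.
# Every generator is a pure function of (parameters, seed).

derive_seed <- function(master_seed, stream) {
  (as.integer(master_seed) + 7919L * as.integer(stream)) %% 2147483629L
}

# banded smoothing matrix with reflected boundaries; smoothing a field is
# S_r %*% M %*% t(S_c)
smoothing_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-half, half)
    # reflect indices that fall off the edge
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (t in seq_along(idx)) S[i, idx[t]] <- S[i, idx[t]] + k[t]
  }
  S
}

#' Smooth Gaussian random field on a grid
#'
#' White noise filtered with a separable Gaussian kernel (reflected
#' boundaries), then standardised to zero mean, unit variance. The kernel
#' width `sigma` (in cells) sets the spatial autocorrelation range.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param sigma Gaussian kernel standard deviation in cells.
#' @return A numeric matrix.
#' @keywords internal
smooth_field <- function(n_rows, n_cols, sigma = 4) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- smoothing_matrix(n_rows, sigma) %*% z %*% t(smoothing_matrix(n_cols, sigma))
  (z - mean(z)) / sd(z)
}

rescale_to <- function(m, lo, hi) {
  r <- range(m)
  if (r[1] == r[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Deterministic south-north temperature gradient
#'
#' The noise-free component of the synthetic bio9 field: warmest at the
#' southern edge, coldest at the northern edge, linear in y.
#'
#' @param grid a [grid_spec()].
#' @param south_value,north_value temperatures (deg C) at the south / north edge.
#' @return Numeric matrix.
#' @export
bio9_gradient <- function(grid, south_value = 20, north_value = -15) {
  y <- cell_centers_y(grid)
  f <- (y - min(y)) / (max(y) - min(y))   # 0 at south row, 1 at north row
  matrix(south_value + f * (north_value - south_value),
         grid$n_rows, grid$n_cols, byrow = FALSE)
}

#' Synthetic national-scale environment
#'
#' Generates the coarse-scale predictor stack: `bio9` (mean temperature of
#' the driest quarter; linear south-north gradient spanning roughly
#' \[-15, 20\] deg C plus smooth correlated noise), `bio14` (precipitation of
#' the driest month, smooth field in \[0, 100\] mm), `bio3` and `bio15`
#' (smooth nuisance fields), and a 6-class categorical `lulc` map
#' (1 cropland, 2 forest, 3 grassland, 4 wetland, 5 impervious, 6 bare).
#'
#' @param grid a [grid_spec()], at least 20 x 20.
#' @param seed integer seed; the stack is deterministic per seed.
#' @param noise_sd amplitude (deg C) of the smooth noise added to the bio9
#'   gradient.
#' @param sigma smoothing kernel width in cells.
#' @return Named list of `hs_raster` layers
#'   (`bio3`, `bio9`, `bio14`, `bio15`, `lulc`).
#' @export
make_national_environment <- function(grid, seed = 1, noise_sd = 1.5, sigma = 4) {
  if (grid$n_rows < 20 || grid$n_cols < 20)
    stop("grid too small to support smoothing: need at least 20 x 20 cells")
  set.seed(seed)
  bio9 <- bio9_gradient(grid) + noise_sd * smooth_field(grid$n_rows, grid$n_cols, sigma)
  bio14 <- rescale_to(smooth_field(grid$n_rows, grid$n_cols, sigma), 0, 100)
  bio3 <- rescale_to(smooth_field(grid$n_rows, grid$n_cols, sigma), 20, 60)
  bio15 <- rescale_to(smooth_field(grid$n_rows, grid$n_cols, sigma), 30, 120)
  class_fields <- lapply(1:6, function(i) smooth_field(grid$n_rows, grid$n_cols, sigma))
  lulc <- matrix(0L, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows))
    for (j in seq_len(grid$n_cols))
      lulc[i, j] <- which.max(vapply(class_fields, function(f) f[i, j], 0))
  list(bio3 = make_raster(grid, bio3),
       bio9 = make_raster(grid, bio9),
       bio14 = make_raster(grid, bio14),
       bio15 = make_raster(grid, bio15),
       lulc = make_raster(grid, lulc, kind = "categorical"))
}

#' Truth model for synthetic suitability
#'
#' Defines the known data-generating suitability: an inverse-logit of an
#' additive predictor with linear + quadratic terms per continuous
#' predictor, an optional exponential distance-to-water decay, and optional
#' per-class land-cover weights. The bio9 coefficients are built from
#' `optimum_bio9` and `bio9_curvature` so the bio9 marginal is unimodal
#' with its maximum exactly at `optimum_bio9`.
#'
#' @param intercept intercept of the linear predictor.
#' @param optimum_bio9 temperature (deg C) at which the bio9 marginal peaks.
#' @param bio9_curvature positive curvature of the bio9 quadratic.
#' @param coefficients named list of `c(linear, quadratic)` per additional
#'   predictor (on the predictor's own units).
#' @param water_decay_distance e-folding distance (m) of the
#'   distance-to-water response, used when the stack has a `dist_water`
#'   layer; `NULL` to disable.
#' @param water_coef logit-scale weight of the water-decay term.
#' @param lulc_class_weights numeric vector in \[0,1\] indexed by class code,
#'   used when the stack has a `lulc` layer; `NULL` to disable.
#' @param lulc_scale logit-scale multiplier applied to the class weights.
#' @return Object of class `truth_model`.
#' @export
truth_model <- function(intercept = -2,
                        optimum_bio9 = 0,
                        bio9_curvature = 0.15,
                        coefficients = list(bio14 = c(0.06, 0)),
                        water_decay_distance = NULL, water_coef = 4,
                        lulc_class_weights = NULL, lulc_scale = 2) {
  stopifnot(bio9_curvature > 0)
  coefficients$bio9 <- c(2 * bio9_curvature * optimum_bio9, -bio9_curvature)
  structure(list(intercept = intercept, coefficients = coefficients,
                 optimum_bio9 = optimum_bio9,
                 water_decay_distance = water_decay_distance,
                 water_coef = water_coef,
                 lulc_class_weights = lulc_class_weights,
                 lulc_scale = lulc_scale),
            class = "truth_model")
}

#' True suitability surface of a synthetic stack
#'
#' Inverse-logit of the truth model's additive predictor evaluated on the
#' stack. Values lie in (0, 1); nodata cells in any used layer propagate.
#'
#' @param stack named list of `hs_raster` layers.
#' @param truth a [truth_model()].
#' @return Continuous `hs_raster`.
#' @export
true_suitability <- function(stack, truth) {
  grid <- stack[[1]]$grid
  eta <- matrix(truth$intercept, grid$n_rows, grid$n_cols)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (nm in names(truth$coefficients)) {
    if (is.null(stack[[nm]]))
      stop("stack is missing predictor required by the truth model: ", nm)
    b <- truth$coefficients[[nm]]
    x <- stack[[nm]]$values
    eta <- eta + b[1] * x + b[2] * x^2
    mask <- mask | stack[[nm]]$nodata_mask
  }
  if (!is.null(truth$water_decay_distance) && !is.null(stack$dist_water)) {
    eta <- eta + truth$water_coef * exp(-stack$dist_water$values / truth$water_decay_distance)
    mask <- mask | stack$dist_water$nodata_mask
  }
  if (!is.null(truth$lulc_class_weights) && !is.null(stack$lulc)) {
    w <- truth$lulc_class_weights[stack$lulc$values]
    eta <- eta + truth$lulc_scale * matrix(w, grid$n_rows, grid$n_cols)
    mask <- mask | stack$lulc$nodata_mask
  }
  p <- stats::plogis(eta)
  p[mask] <- NA
  make_raster(grid, p, mask, kind = "continuous")
}

#' Occurrence set
#'
#' Presence or background points in map coordinates.
#'
#' @param x,y numeric coordinate vectors.
#' @param label `"presence"` or `"background"`.
#' @return data.frame with columns `x`, `y`, `label`, class `occurrence_set`.
#' @export
occurrence_set <- function(x, y, label = "presence") {
  label <- match.arg(label, c("presence", "background"))
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       label = rep_len(label, length(x))),
            class = c("occurrence_set", "data.frame"))
}

#' Sample occurrences from a suitability truth
#'
#' Draws `n` cells without replacement with probability proportional to
#' suitability and places one point at each sampled cell centre.
#'
#' @param suitability continuous `hs_raster` with values in \[0,1\].
#' @param n number of presences.
#' @param seed integer seed.
#' @return An [occurrence_set()] of `n` presence points.
#' @export
sample_occurrences <- function(suitability, n, seed = 1) {
  stopifnot(n >= 1)
  g <- suitability$grid
  p <- as.vector(suitability$values)
  p[as.vector(suitability$nodata_mask)] <- 0
  p[is.na(p)] <- 0
  pos <- which(p > 0)
  if (n > length(pos))
    stop("n exceeds the ", length(pos), " cells with positive suitability")
  set.seed(seed)
  idx <- pos[sample.int(length(pos), n, prob = p[pos])]
  row <- (idx - 1) %% g$n_rows + 1
  col <- (idx - 1) %/% g$n_rows + 1
  occurrence_set(cell_centers_x(g)[col], cell_centers_y(g)[row], "presence")
}

# slope (degrees) and aspect (degrees clockwise from north) from an
# elevation matrix by centred finite differences (one-sided at edges)
terrain_slope_aspect <- function(elev, cell_m) {
  nr <- nrow(elev); nc <- ncol(elev)
  ex <- cbind(elev[, 1], elev, elev[, nc])
  ey <- rbind(elev[1, ], elev, elev[nr, ])
  dzdx <- (ex[, 3:(nc + 2)] - ex[, 1:nc]) / (2 * cell_m)
  dzdy <- (ey[3:(nr + 2), ] - ey[1:nr, ]) / (2 * cell_m)
  list(slope = atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi,
       aspect = (atan2(dzdy, -dzdx) * 180 / pi) %% 360)
}

# Euclidean distance (map units) from every cell centre to the nearest
# target cell centre; brute force over target cells, fine at study sizes.
distance_to_cells <- function(grid, target_rc, unit_m_per_map_unit = 1) {
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  tx <- cx[target_rc[, 2]]; ty <- cy[target_rc[, 1]]
  d2 <- matrix(Inf, grid$n_rows, grid$n_cols)
  X <- matrix(cx, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(cy, grid$n_rows, grid$n_cols)
  for (k in seq_along(tx)) d2 <- pmin(d2, (X - tx[k])^2 + (Y - ty[k])^2)
  sqrt(d2) * unit_m_per_map_unit
}

metres_per_map_unit <- function(grid) {
  if (grid$crs_tag == "lonlat") 111320 else 1
}

#' Synthetic provincial-scale environment
#'
#' Generates the fine-scale stack: smooth `elevation` (m); `slope` (deg)
#' and `aspect` (deg) from elevation by centred finite differences; a
#' random-walk river polyline, with `dist_water` the Euclidean distance
#' (m) to it; a straight north-south road, with `dist_road` likewise;
#' a sparse `nightlight` field; and a 6-class `lulc` map with wetland
#' forced along the river. Distances on lonlat grids use 111.32 km per
#' degree.
#'
#' @param grid a [grid_spec()], at least 20 x 20.
#' @param seed integer seed.
#' @param sigma smoothing kernel width in cells.
#' @return Named list of `hs_raster` layers (`aspect`, `elevation`,
#'   `slope`, `lulc`, `nightlight`, `dist_road`, `dist_water`), plus the
#'   river cells as attribute `river_cells`.
#' @export
make_provincial_environment <- function(grid, seed = 1, sigma = 5) {
  if (grid$n_rows < 20 || grid$n_cols < 20)
    stop("grid too small to support smoothing: need at least 20 x 20 cells")
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  m_per_unit <- metres_per_map_unit(grid)
  cell_m <- grid$cell_size * m_per_unit

  elev <- rescale_to(smooth_field(nr, nc, sigma), 300, 2000)
  terr <- terrain_slope_aspect(elev, cell_m)
  slope <- terr$slope; aspect <- terr$aspect

  river_col <- integer(nr)
  river_col[1] <- sample(seq(ceiling(nc * 0.3), floor(nc * 0.7)), 1)
  for (i in 2:nr)
    river_col[i] <- min(nc, max(1, river_col[i - 1] + sample(-1:1, 1)))
  river_rc <- cbind(seq_len(nr), river_col)
  dist_water <- distance_to_cells(grid, river_rc, m_per_unit)

  road_col <- sample(seq_len(nc), 1)
  x_road <- cell_centers_x(grid)[road_col]
  dist_road <- matrix(abs(cell_centers_x(grid) - x_road) * m_per_unit,
                      nr, nc, byrow = TRUE)

  nl <- smooth_field(nr, nc, sigma / 2)
  nightlight <- rescale_to(pmax(nl - 1, 0)^2, 0, 63)   # sparse bright spots

  class_fields <- lapply(1:6, function(i) smooth_field(nr, nc, sigma))
  lulc <- matrix(0L, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      lulc[i, j] <- which.max(vapply(class_fields, function(f) f[i, j], 0))
  lulc[dist_water <= 1.5 * cell_m] <- 4L   # wetland corridor along the river

  out <- list(aspect = make_raster(grid, aspect),
              elevation = make_raster(grid, elev),
              slope = make_raster(grid, slope),
              lulc = make_raster(grid, lulc, kind = "categorical"),
              nightlight = make_raster(grid, nightlight),
              dist_road = make_raster(grid, dist_road),
              dist_water = make_raster(grid, dist_water))
  attr(out, "river_cells") <- river_rc
  out
}

#' Synthetic land-cover time series with a known transition rule
#'
#' Builds a 6-class mosaic at t0 with an impervious seed patch at the urban
#' centre, then produces t1 and t2 by a known deterministic rule: grassland
#' cells within distance `d` (m) of the urban centre convert to impervious,
#' with `d = growth_distance` at t1 and `2 * growth_distance` at t2.
#' The rule parameters are recorded so recovery tests can recompute the
#' conversions independently.
#'
#' @param grid a [grid_spec()].
#' @param drivers optional named list with a `dist_urban` `hs_raster`
#'   (m to the urban centre); generated from the grid centre when `NULL`.
#' @param seed integer seed.
#' @param growth_distance conversion radius increment per step (m);
#'   0 freezes the series.
#' @param sigma smoothing width for the t0 mosaic.
#' @param class_bias additive prevalence bias per class before the
#'   argmax; the default favours cropland and grassland, the dominant
#'   cover of the emulated landscape, so the conversion rule has material
#'   to act on.
#' @return List with `lulc_t0`, `lulc_t1`, `lulc_t2` (categorical
#'   `hs_raster`s), `drivers` (with `dist_urban`), and `rule`
#'   (urban centre cell, radii `d1`, `d2`, classes involved).
#' @export
make_lulc_series <- function(grid, drivers = NULL, seed = 1,
                             growth_distance = 4500, sigma = 4,
                             class_bias = c(0.3, 0.2, 0.6, -0.2, -0.3, -0.2)) {
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  m_per_unit <- metres_per_map_unit(grid)
  if (is.null(drivers)) drivers <- list()
  if (is.null(drivers$dist_urban)) {
    centre <- cbind(round(nr / 2), round(nc / 2))
    drivers$dist_urban <- make_raster(grid, distance_to_cells(grid, centre, m_per_unit))
  }
  du <- drivers$dist_urban$values
  class_fields <- lapply(1:6, function(i)
    smooth_field(nr, nc, sigma) + class_bias[i])
  t0 <- matrix(0L, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      t0[i, j] <- which.max(vapply(class_fields, function(f) f[i, j], 0))
  t0[du <= 2 * grid$cell_size * m_per_unit] <- 5L   # impervious seed patch

  convert <- function(m, d) { m[m == 3L & du <= d] <- 5L; m }
  d1 <- growth_distance; d2 <- 2 * growth_distance
  t1 <- convert(t0, d1)
  t2 <- convert(t1, d2)
  list(lulc_t0 = make_raster(grid, t0, kind = "categorical"),
       lulc_t1 = make_raster(grid, t1, kind = "categorical"),
       lulc_t2 = make_raster(grid, t2, kind = "categorical"),
       drivers = drivers,
       rule = list(d1 = d1, d2 = d2, from_class = 3L, to_class = 5L))
}

#' Scenario specification
#'
#' A future-climate scenario: an SSP family and period with a temperature
#' delta (deg C, added to bio9) and a precipitation factor (applied to
#' bio14 and bio15). Default deltas are stand-ins ordered as the scenario
#' families are: +0.5/+1.0/+1.5 deg C (2030s) and +0.8/+1.5/+2.5 deg C
#' (2050s) for SSP126/SSP245/SSP585.
#'
#' @param scenario_id one of `"SSP126"`, `"SSP245"`, `"SSP585"`.
#' @param period `"2030s"` or `"2050s"`.
#' @param temperature_delta,precipitation_factor overrides; defaults come
#'   from the built-in table.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, period,
                          temperature_delta = NULL, precipitation_factor = NULL) {
  scenario_id <- match.arg(scenario_id, c("SSP126", "SSP245", "SSP585"))
  period <- match.arg(period, c("2030s", "2050s"))
  deltas <- list("2030s" = c(SSP126 = 0.5, SSP245 = 1.0, SSP585 = 1.5),
                 "2050s" = c(SSP126 = 0.8, SSP245 = 1.5, SSP585 = 2.5))
  pfacs <- list("2030s" = c(SSP126 = 1.02, SSP245 = 1.04, SSP585 = 1.06),
                "2050s" = c(SSP126 = 1.03, SSP245 = 1.06, SSP585 = 1.10))
  if (is.null(temperature_delta)) temperature_delta <- deltas[[period]][[scenario_id]]
  if (is.null(precipitation_factor)) precipitation_factor <- pfacs[[period]][[scenario_id]]
  structure(list(scenario_id = scenario_id, period = period,
                 temperature_delta = temperature_delta,
                 precipitation_factor = precipitation_factor),
            class = "scenario_spec")
}

#' Apply a climate scenario to a stack
#'
#' Adds the scenario's temperature delta to `bio9` and multiplies `bio14`
#' and `bio15` by its precipitation factor; all other layers pass through
#' unchanged.
#'
#' @param stack named list of `hs_raster` layers.
#' @param scenario a [scenario_spec()].
#' @return A stack of the same shape.
#' @export
make_future_climate <- function(stack, scenario) {
  out <- stack
  if (!is.null(out$bio9))
    out$bio9$values <- out$bio9$values + scenario$temperature_delta
  for (nm in c("bio14", "bio15"))
    if (!is.null(out[[nm]]))
      out[[nm]]$values <- out[[nm]]$values * scenario$precipitation_factor
  out
}

#' Random protected-area mask
#'
#' Unions random circular blobs until approximately `fraction` of the
#' cells are covered (within 10 percent relative); each blob covers about
#' 5 percent of the target so the overshoot stays small.
#'
#' @param grid a [grid_spec()].
#' @param fraction target covered fraction in \[0,1\].
#' @param seed integer seed.
#' @return Binary `hs_raster`.
#' @export
make_protected_areas <- function(grid, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  nr <- grid$n_rows; nc <- grid$n_cols
  m <- matrix(0, nr, nc)
  if (fraction >= 0.999) return(make_raster(grid, m + 1, kind = "binary"))
  if (fraction > 0) {
    set.seed(seed)
    target <- fraction * nr * nc
    radius <- max(1, sqrt(0.05 * target / pi))
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    guard <- 0
    while (sum(m) < target && guard < 10000) {
      ci <- runif(1, 1, nr); cj <- runif(1, 1, nc)
      m[(rows - ci)^2 + (cols - cj)^2 <= radius^2] <- 1
      guard <- guard + 1
    }
  }
  make_raster(grid, m, kind = "binary")
}
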