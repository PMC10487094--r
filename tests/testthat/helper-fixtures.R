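# Shared fixtures, built in code.

# small flat grid: n x n cells of `cell` metres
ea_grid <- function(n = 10, cell = 300)
  grid_spec(n, n, x_origin = 0, y_origin = n * cell, cell_size = cell)

ll_grid <- function(n_rows = 40, n_cols = 30, lat_top = 40, lon_left = 100,
                    cell = 0.2)
  grid_spec(n_rows, n_cols, x_origin = lon_left, y_origin = lat_top,
            cell_size = cell, crs_tag = "lonlat")

binary_raster <- function(grid, ones_idx = integer(0)) {
  v <- matrix(0, grid$n_rows, grid$n_cols)
  v[ones_idx] <- 1
  make_raster(grid, v, kind = "binary")
}

random_binary <- function(grid, p = 0.4, seed = 1) {
  set.seed(seed)
  make_raster(grid, matrix(rbinom(grid$n_rows * grid$n_cols, 1, p),
                           grid$n_rows, grid$n_cols), kind = "binary")
}

# linearly separable presence/background toy table
separable_table <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  x1 <- c(rnorm(n_per_class, 2, 0.3), rnorm(n_per_class, -2, 0.3))
  x2 <- c(rnorm(n_per_class, 1, 0.5), rnorm(n_per_class, -1, 0.5))
  structure(data.frame(x1 = x1, x2 = x2,
                       response = rep(c(1, 0), each = n_per_class)),
            predictor_names = c("x1", "x2"))
}

# noise-only table: response carries no signal
noise_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  structure(data.frame(x1 = rnorm(n), x2 = rnorm(n),
                       response = rep(c(1, 0), length.out = n)),
            predictor_names = c("x1", "x2"))
}

# brute-force AUC oracle: enumerate all presence/background pairs
auc_bruteforce <- function(obs, scores) {
  sp <- scores[obs == 1]; sb <- scores[obs == 0]
  wins <- 0
  for (a in sp) for (b in sb) wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(sp) * length(sb))
}

# exhaustive MTSS oracle
mtss_bruteforce <- function(obs, scores) {
  cand <- sort(unique(scores))
  best <- -Inf; best_t <- NA
  for (t in cand) {
    ss <- mean(scores[obs == 1] >= t) + mean(scores[obs == 0] < t)
    if (ss > best + 1e-15) { best <- ss; best_t <- t }
  }
  best_t
}

# small national-truth SDM setup used by several tests
small_sdm_fixture <- function(seed = 7, n = 150, grid = ll_grid(30, 30)) {
  env <- make_national_environment(grid, seed = seed)
  suit <- true_suitability(env, truth_model())
  occ <- thin_occurrences(sample_occurrences(suit, n, seed = seed + 1),
                          grid, seed = seed + 2)
  bg <- sample_background(grid, n, exclude = occ, seed = seed + 3)
  list(grid = grid, env = env, suit = suit, occ = occ, bg = bg,
       table = build_training_table(env, occ, bg))
}
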