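# End-to-end orchestration on the synthetic study system: national
# (coarse, climate) ensemble projected to future scenarios, provincial
# (fine, local) ensemble under simulated land-use change, and the
# hierarchical combination with refugia, change, latitudinal-profile and
# protected-area reports. One config list, one master seed.

#' Default pipeline configuration
#'
#' A single list drives the whole pipeline. The default grids are a
#' coarse lonlat "national" grid (0.2 degree cells, lat 28-42 N) with a
#' nested fine "provincial" grid (0.05 degree cells, lat 31-39 N), so
#' latitudinal profiles and the cross-scale overlay are both exercised.
#' The master seed propagates to every stochastic stage.
#'
#' @param master_seed integer master seed.
#' @param n_runs evaluation splits per ensemble (default 5 here; see
#'   [fit_ensemble()] for the per-call default of 10).
#' @param algorithms member algorithms to fit.
#' @return Named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(master_seed = 1, n_runs = 5,
                                    algorithms = ALGORITHMS) {
  structure(list(
    master_seed = master_seed,
    national_grid = grid_spec(70, 60, x_origin = 104, y_origin = 42,
                              cell_size = 0.2, crs_tag = "lonlat"),
    provincial_grid = grid_spec(160, 120, x_origin = 106, y_origin = 39,
                                cell_size = 0.05, crs_tag = "lonlat"),
    national_truth = truth_model(intercept = -2, optimum_bio9 = 0,
                                 bio9_curvature = 0.15,
                                 coefficients = list(bio14 = c(0.06, 0))),
    provincial_truth = truth_model(intercept = -2.5, optimum_bio9 = 4,
                                   bio9_curvature = 0.05,
                                   coefficients = list(),
                                   water_decay_distance = 15000, water_coef = 3,
                                   lulc_class_weights =
                                     c(0.4, 0.2, 0.2, 1.0, 0.6, 0.1),
                                   lulc_scale = 2),
    n_presence_national = 400, n_background_national = 400,
    n_presence_provincial = 300, n_background_provincial = 300,
    algorithms = algorithms, n_runs = n_runs,
    correlation_threshold = 0.75,
    scenarios = expand.grid(scenario_id = c("SSP126", "SSP245", "SSP585"),
                            period = c("2030s", "2050s"),
                            stringsAsFactors = FALSE),
    lulc_growth_distance = 100000,
    pa_fractions = c(reserves = 0.03, wetland_parks = 0.005),
    profile_bandwidth = 0.1
  ), class = "pipeline_config")
}

# provincial truth needs a bio9-like driver absent from the local stack;
# drop its bio9 term by rebuilding without it
strip_bio9 <- function(truth) {
  truth$coefficients$bio9 <- NULL
  truth
}

#' Run the national (coarse, climate) stage
#'
#' Generates the coarse environment and truth suitability, samples and
#' thins occurrences, draws background, screens predictors, fits the
#' TSS-weighted ensemble, and binarizes the current and each scenario
#' suitability map at the ensemble MTSS threshold. Only this
#' national-scale model is projected to future climates.
#'
#' @param config a [default_pipeline_config()] list.
#' @return List: `env`, `truth_suitability`, `table`, `ensemble`,
#'   `mtss`, `current` (continuous), `current_binary`, `scenarios`
#'   (data.frame), `scenario_maps` (named list with `suitability` and
#'   `binary` per scenario), `evaluation` (per-run mean metrics).
#' @export
run_national <- function(config) {
  cfg <- config
  seed <- cfg$master_seed
  env <- make_national_environment(cfg$national_grid, seed = derive_seed(seed, 1))
  truth_map <- true_suitability(env, cfg$national_truth)
  occ_raw <- sample_occurrences(truth_map, cfg$n_presence_national,
                                seed = derive_seed(seed, 2))
  occ <- thin_occurrences(occ_raw, cfg$national_grid, seed = derive_seed(seed, 3))
  bg <- sample_background(cfg$national_grid, cfg$n_background_national,
                          exclude = occ, seed = derive_seed(seed, 4))
  table <- build_training_table(env, occ, bg)
  kept <- select_predictors(table, threshold = cfg$correlation_threshold)
  table <- structure(table[c(kept, "response")],
                     predictor_names = intersect(attr(table, "predictor_names"),
                                                 c(kept, names(attr(table, "groups")))),
                     groups = attr(table, "groups"),
                     encoding = attr(table, "encoding"))
  ens <- fit_ensemble(table, algorithms = cfg$algorithms, n_runs = cfg$n_runs,
                      master_seed = derive_seed(seed, 5))
  current <- ensemble_predict(ens, env)
  current_binary <- binarize(current, ens$mtss_threshold)
  scenario_maps <- list()
  for (i in seq_len(nrow(cfg$scenarios))) {
    sc <- scenario_spec(cfg$scenarios$scenario_id[i], cfg$scenarios$period[i])
    fut_env <- make_future_climate(env, sc)
    suit <- ensemble_predict(ens, fut_env)
    key <- paste(sc$scenario_id, sc$period, sep = "_")
    scenario_maps[[key]] <- list(spec = sc, suitability = suit,
                                 binary = binarize(suit, ens$mtss_threshold))
  }
  list(env = env, truth_suitability = truth_map, occurrences = occ,
       background = bg, table = table, ensemble = ens,
       mtss = ens$mtss_threshold, current = current,
       current_binary = current_binary, scenarios = cfg$scenarios,
       scenario_maps = scenario_maps, evaluation = evaluation_summary(ens))
}

#' Run the provincial (fine, local) stage
#'
#' As [run_national()] but on the fine local stack (topography, human
#' influence, water, land cover). Futures swap only the land-cover layer
#' for CA-simulated maps — the provincial model is never projected to
#' future climate. The historical pair for the CA is the known-rule
#' series from [make_lulc_series()]: its t1 plays the current map, demand
#' and transition suitability are learned from t0 to t1, and the 2030s /
#' 2050s maps are simulated forward.
#'
#' @param config a [default_pipeline_config()] list.
#' @return List: `env`, `table`, `ensemble`, `mtss`, `current`,
#'   `current_binary`, `future` (per period: `lulc`, `suitability`,
#'   `binary`), `ca_validation` (hold-out agreement of the CA against the
#'   rule-generated t2), `evaluation`.
#' @export
run_provincial <- function(config) {
  cfg <- config
  seed <- cfg$master_seed
  grid <- cfg$provincial_grid
  env <- make_provincial_environment(grid, seed = derive_seed(seed, 11))
  series <- make_lulc_series(grid, seed = derive_seed(seed, 12),
                             growth_distance = cfg$lulc_growth_distance)
  env$lulc <- series$lulc_t1   # current land cover
  truth <- strip_bio9(cfg$provincial_truth)
  truth_map <- true_suitability(env, truth)
  occ_raw <- sample_occurrences(truth_map, cfg$n_presence_provincial,
                                seed = derive_seed(seed, 13))
  occ <- thin_occurrences(occ_raw, grid, seed = derive_seed(seed, 14))
  bg <- sample_background(grid, cfg$n_background_provincial,
                          exclude = occ, seed = derive_seed(seed, 15))
  table <- build_training_table(env, occ, bg)
  ens <- fit_ensemble(table, algorithms = cfg$algorithms, n_runs = cfg$n_runs,
                      master_seed = derive_seed(seed, 16))
  current <- ensemble_predict(ens, env)
  current_binary <- binarize(current, ens$mtss_threshold)

  drivers <- list(dist_urban = series$drivers$dist_urban,
                  elevation = env$elevation, dist_road = env$dist_road)
  trans <- fit_transition_model(series$lulc_t0, series$lulc_t1, drivers,
                                seed = derive_seed(seed, 17))
  sim_t2 <- simulate_lulc(series$lulc_t1, trans,
                          estimate_demand(series$lulc_t0, series$lulc_t1, 10, 10),
                          seed = derive_seed(seed, 18))
  ca_validation <- map_agreement(sim_t2, series$lulc_t2)

  future <- list()
  horizon <- c("2030s" = 10, "2050s" = 30)
  for (per in names(horizon)) {
    dem <- estimate_demand(series$lulc_t0, series$lulc_t1, 10, horizon[[per]])
    lulc_fut <- simulate_lulc(series$lulc_t1, trans, dem,
                              seed = derive_seed(seed, 19 + horizon[[per]]))
    fut_env <- env
    fut_env$lulc <- lulc_fut
    suit <- ensemble_predict(ens, fut_env)
    future[[per]] <- list(lulc = lulc_fut, suitability = suit,
                          binary = binarize(suit, ens$mtss_threshold))
  }
  list(env = env, lulc_series = series, table = table, ensemble = ens,
       mtss = ens$mtss_threshold, current = current,
       current_binary = current_binary, future = future,
       ca_validation = ca_validation, evaluation = evaluation_summary(ens))
}

#' Run the full hierarchical analysis
#'
#' Runs both stages, then per scenario x period: intersects the national
#' climatic binary (resampled to the fine grid) with the provincial local
#' binary of the matching period, accounts stable/gain/lost area versus
#' the current final map, and reports latitudinal profiles, climate
#' refugia (intersection of the current climatic map with all scenario
#' futures) and protected-area coverage.
#'
#' @param config a [default_pipeline_config()] list.
#' @return List: `national`, `provincial`, `current_final`
#'   (combine_scales output for the present), `scenario_results` (per
#'   scenario: the combined maps plus a `change_report`), `change_table`
#'   (Table-5-shaped data.frame), `refugia`, `refugia_km2`,
#'   `gap_table`, `profiles` (latitudinal profiles of the current and
#'   scenario final maps).
#' @export
run_hierarchical <- function(config) {
  cfg <- config
  nat <- run_national(cfg)
  prov <- run_provincial(cfg)

  cur <- combine_scales(nat$current_binary, prov$current, prov$mtss)
  results <- list(); rows <- list(); profiles <- list()
  profiles$current <- latitudinal_profile(cur$final_binary, cfg$profile_bandwidth)
  for (key in names(nat$scenario_maps)) {
    sm <- nat$scenario_maps[[key]]
    per <- sm$spec$period
    comb <- combine_scales(sm$binary, prov$future[[per]]$suitability, prov$mtss)
    rep <- change_accounting(cur$final_binary, comb$final_binary)
    results[[key]] <- c(comb, list(change = rep))
    profiles[[key]] <- latitudinal_profile(comb$final_binary, cfg$profile_bandwidth)
    rows[[key]] <- data.frame(scenario = sm$spec$scenario_id, period = per,
                              stable_km2 = rep$stable_km2, gain_km2 = rep$gain_km2,
                              lost_km2 = rep$lost_km2,
                              final_km2 = rep$future_km2,
                              pct_change = rep$percent_change_vs_current)
  }
  change_table <- do.call(rbind, rows)
  rownames(change_table) <- NULL

  fut_binaries <- lapply(nat$scenario_maps, `[[`, "binary")
  ref <- refugia(nat$current_binary, fut_binaries)

  masks <- lapply(stats::setNames(nm = names(cfg$pa_fractions)), function(nm)
    make_protected_areas(cfg$provincial_grid, cfg$pa_fractions[[nm]],
                         seed = derive_seed(cfg$master_seed, 30 + match(nm, names(cfg$pa_fractions)))))
  gap <- protected_gap(cur$final_binary, masks)

  list(national = nat, provincial = prov, current_final = cur,
       scenario_results = results, change_table = change_table,
       refugia = ref, refugia_km2 = area_km2(ref),
       pa_masks = masks, gap_table = gap, profiles = profiles)
}
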