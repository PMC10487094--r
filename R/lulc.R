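# Simplified patch-generating land-use change simulation: per-class demand
# extrapolation, a learned transition-suitability surface (expansion cells
# vs a matched sample of unchanged cells, probability random forest), a
# seeded cellular automaton that allocates conversions by roulette wheel
# with neighbourhood reinforcement and random patch seeding, and
# OA / Kappa map-agreement validation.

LULC_CLASSES <- c(cropland = 1, forest = 2, grassland = 3,
                  wetland = 4, impervious = 5, bare = 6)

class_counts <- function(map, classes = LULC_CLASSES) {
  v <- map$values[!map$nodata_mask]
  vapply(classes, function(k) sum(v == k), 0)
}

# largest-remainder rounding of a nonnegative vector to integers with a
# fixed total
round_to_total <- function(x, total) {
  x <- pmax(x, 0)
  if (sum(x) == 0) x <- rep(1, length(x))
  scaled <- x / sum(x) * total
  base <- floor(scaled)
  short <- total - sum(base)
  if (short > 0) {
    give <- order(scaled - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  base
}

#' Extrapolated land-use demand
#'
#' Per class, the linear extrapolation of the net change between two
#' historical maps: `D_c = A_c(t2) + (A_c(t2) - A_c(t1)) * years_ahead /
#' years_between`, clamped at zero and rescaled (largest-remainder) so the
#' demands sum exactly to the total cell count.
#'
#' @param map_t1,map_t2 categorical `hs_raster`s on the same grid.
#' @param years_between years separating the historical maps.
#' @param years_ahead years from `map_t2` to the target horizon.
#' @param classes named class-code vector (default the 6 general classes).
#' @return Named integer vector of target cell counts per class.
#' @export
estimate_demand <- function(map_t1, map_t2, years_between, years_ahead,
                            classes = LULC_CLASSES) {
  stopifnot(years_between > 0)
  n1 <- class_counts(map_t1, classes)
  n2 <- class_counts(map_t2, classes)
  d <- n2 + (n2 - n1) * years_ahead / years_between
  total <- sum(!map_t2$nodata_mask)
  stats::setNames(round_to_total(d, total), names(classes))
}

#' Transition-suitability surfaces from historical expansion
#'
#' For each class `c`, cells that changed into `c` between the two maps
#' are the positives and an equal-sized seeded sample of cells that did
#' not are the negatives; a probability random forest on the driver values
#' then yields a transition-suitability surface `P_c` over the whole grid.
#' Classes with no expansion cells get a zero surface with a warning.
#'
#' @param map_t1,map_t2 categorical `hs_raster`s.
#' @param drivers named list of continuous `hs_raster` driver layers.
#' @param seed integer seed.
#' @param classes named class-code vector.
#' @return Named list of continuous `hs_raster`s (one `P_c` per class),
#'   class `transition_suitability`.
#' @export
fit_transition_model <- function(map_t1, map_t2, drivers, seed = 1,
                                 classes = LULC_CLASSES) {
  grid <- map_t1$grid
  drv <- data.frame(lapply(drivers, function(l) as.vector(l$values)))
  t1 <- as.vector(map_t1$values); t2 <- as.vector(map_t2$values)
  valid <- !as.vector(map_t1$nodata_mask | map_t2$nodata_mask)
  out <- list()
  for (nm in names(classes)) {
    k <- classes[[nm]]
    pos <- which(valid & t1 != k & t2 == k)
    if (length(pos) == 0) {
      warning("class '", nm, "' has no expansion cells; using a zero surface")
      out[[nm]] <- make_raster(grid, matrix(0, grid$n_rows, grid$n_cols))
      next
    }
    set.seed(derive_seed(seed, k))
    neg_pool <- which(valid & t2 != k)
    neg <- neg_pool[sample.int(length(neg_pool), min(length(pos), length(neg_pool)))]
    idx <- c(pos, neg)
    y <- factor(rep(c(1, 0), c(length(pos), length(neg))), levels = c(0, 1))
    rf <- ranger::ranger(x = drv[idx, , drop = FALSE], y = y,
                         probability = TRUE, num.trees = 300,
                         seed = derive_seed(seed, k))
    p <- stats::predict(rf, data = drv)$predictions[, "1"]
    # at the cells the forest was trained on, use its out-of-bag
    # probabilities: plain refitting probabilities there are memorized
    # (near 0/1) and would paint an overfit halo into the surface
    oob <- rf$predictions[, "1"]
    p[idx[!is.na(oob)]] <- oob[!is.na(oob)]
    v <- matrix(p, grid$n_rows, grid$n_cols)
    v[map_t1$nodata_mask] <- NA
    out[[nm]] <- make_raster(grid, v, map_t1$nodata_mask)
  }
  structure(out, class = c("transition_suitability", "list"))
}

# fraction of class-k cells in the 3x3 Moore neighbourhood of every cell
neighbourhood_fraction <- function(map_values, k) {
  ind <- (map_values == k) * 1
  nr <- nrow(ind); nc <- ncol(ind)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- ind
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  ones <- matrix(1, nr + 2, nc + 2); ones[] <- 0
  ones[2:(nr + 1), 2:(nc + 1)] <- 1
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    acc <- acc + z[2:(nr + 1) + di, 2:(nc + 1) + dj]
    cnt <- cnt + ones[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  acc / pmax(cnt, 1)
}

#' Patch-generating CA allocation of land-use change
#'
#' Iteratively converts cells until every class is within tolerance of its
#' demand. Per sweep and growing class `c`, a donor cell's overall
#' conversion probability is `OP_c = P_c * (w * N_c + (1 - w))`, with
#' `N_c` the class-`c` fraction of its 3x3 Moore neighbourhood; cells with
#' `N_c = 0` are only eligible with probability `seed_prob` per sweep
#' (random patch seeding), in which case `P_c` alone drives them.
#' Candidates above the acceptance threshold are drawn by a seeded
#' roulette wheel (probability proportional to `OP_c`); donors are cells
#' of classes above demand, and a donor class never drops below its own
#' demand. The acceptance threshold decays by `decay` each sweep. Total
#' cell count is conserved at every iteration.
#'
#' @param map_t0 starting categorical `hs_raster`.
#' @param suit a [fit_transition_model()] result.
#' @param demand named demand vector from [estimate_demand()]; must sum to
#'   the non-nodata cell count.
#' @param params list: `neighborhood_weight` (w, default 0.9), `decay`
#'   (default 0.9), `seed_prob` (default 0.01), `max_iters` (default 60),
#'   `tolerance` (fraction of total cells, default 0.01).
#' @param seed integer seed.
#' @param classes named class-code vector.
#' @return Categorical `hs_raster`, with attribute `iterations`.
#' @export
simulate_lulc <- function(map_t0, suit, demand, params = list(), seed = 1,
                          classes = LULC_CLASSES) {
  p <- utils::modifyList(list(neighborhood_weight = 0.9, decay = 0.9,
                              seed_prob = 0.01, max_iters = 60,
                              tolerance = 0.01), params)
  total <- sum(!map_t0$nodata_mask)
  if (sum(demand) > total)
    stop("infeasible demand: ", sum(demand), " cells demanded, ", total, " available")
  m <- map_t0$values
  valid <- !map_t0$nodata_mask
  tol_cells <- max(1, ceiling(p$tolerance * total))
  set.seed(seed)
  thr <- 0.8
  iters <- 0
  for (sweep in seq_len(p$max_iters)) {
    counts <- vapply(classes, function(k) sum(m[valid] == k), 0)
    gap <- demand - counts
    if (all(abs(gap) <= tol_cells)) break
    iters <- sweep
    growing <- names(classes)[gap > 0]
    donors_cls <- classes[gap < 0]
    if (!length(growing) || !length(donors_cls)) break
    donor_budget <- -gap[gap < 0]   # cells each donor class may still give up
    for (g in growing) {
      k <- classes[[g]]
      need <- demand[[g]] - sum(m[valid] == k)
      if (need <= 0) next
      Nk <- neighbourhood_fraction(m, k)
      # floor keeps the roulette defined where the learned surface is
      # exactly zero; the neighbourhood term then drives the ranking
      Pg <- pmax(suit[[g]]$values, 1e-6)
      OP <- Pg * (p$neighborhood_weight * Nk + (1 - p$neighborhood_weight))
      cand <- which(valid & (m %in% donors_cls))
      seeded <- stats::runif(length(cand)) < p$seed_prob
      eligible <- Nk[cand] > 0 | seeded
      score <- ifelse(Nk[cand] > 0, OP[cand], Pg[cand])
      cand <- cand[eligible]; score <- score[eligible]
      if (!length(cand)) next
      # decaying acceptance threshold; once it lapses below every
      # candidate the roulette weights alone decide, so allocation always
      # proceeds toward demand
      keep <- score >= thr
      if (!any(keep)) keep <- rep(TRUE, length(score))
      cand <- cand[keep]; score <- score[keep]
      take <- min(need, length(cand))
      pick <- cand[sample.int(length(cand), take, prob = score)]
      # respect donor budgets: convert in pick order while budget lasts
      for (cell in pick) {
        dnm <- names(classes)[match(m[cell], classes)]
        if (is.na(dnm) || donor_budget[dnm] <= 0) next
        m[cell] <- k
        donor_budget[dnm] <- donor_budget[dnm] - 1
      }
    }
    thr <- thr * p$decay
  }
  out <- make_raster(map_t0$grid, m, map_t0$nodata_mask, kind = "categorical")
  attr(out, "iterations") <- iters
  out
}

#' Agreement between two categorical maps
#'
#' Overall accuracy (matching-cell fraction) and the multi-class Kappa
#' coefficient with the standard marginal expected agreement, plus the
#' full confusion matrix.
#'
#' @param simulated,actual categorical `hs_raster`s on the same grid.
#' @return List of class `map_agreement_report`: `overall_accuracy`,
#'   `kappa`, `confusion` (classes of `actual` in columns).
#' @export
map_agreement <- function(simulated, actual) {
  if (!grids_identical(simulated$grid, actual$grid))
    stop("grid mismatch in map_agreement")
  ok <- !(simulated$nodata_mask | actual$nodata_mask)
  s <- simulated$values[ok]; a <- actual$values[ok]
  levs <- sort(unique(c(s, a)))
  cm <- table(factor(s, levels = levs), factor(a, levels = levs))
  n <- sum(cm)
  oa <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (isTRUE(all.equal(pe, 1))) NA_real_ else (oa - pe) / (1 - pe)
  structure(list(overall_accuracy = oa, kappa = kappa, confusion = cm),
            class = "map_agreement_report")
}

#' @export
print.map_agreement_report <- function(x, ...) {
  cat(sprintf("<map_agreement> OA = %.3f, Kappa = %.3f\n",
              x$overall_accuracy, x$kappa))
  invisible(x)
}
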