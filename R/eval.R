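# Presence-background model evaluation: confusion counts, the
# threshold-dependent metrics (Kappa, TSS, Jaccard, Sorensen, Fpb), the
# rank AUC, the continuous Boyce index, the MTSS threshold, permutation
# variable importance and response-curve extraction.

#' Confusion counts at a threshold
#'
#' A point is predicted present iff its score is `>= threshold`.
#'
#' @param obs 0/1 observed labels (1 = presence).
#' @param scores numeric suitability scores.
#' @param threshold decision threshold.
#' @return List of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(obs, scores, threshold) {
  stopifnot(length(obs) == length(scores))
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1 & obs == 1), FP = sum(pred == 1 & obs == 0),
                 FN = sum(pred == 0 & obs == 1), TN = sum(pred == 0 & obs == 0)),
            class = "confusion_counts")
}

#' Threshold-dependent metrics from confusion counts
#'
#' \describe{
#'   \item{TSS}{sensitivity + specificity - 1}
#'   \item{Kappa}{chance-corrected agreement with the standard marginal
#'     expected agreement}
#'   \item{Jaccard}{TP / (TP + FP + FN)}
#'   \item{Sorensen}{2 TP / (2 TP + FP + FN)}
#'   \item{Fpb}{the F-measure on presence-background counts, identical in
#'     form to Sorensen with background standing in for absences}
#' }
#' An empty class margin makes the affected metric `NA` (undefined), not 0.
#'
#' @param c a [confusion()] result.
#' @return Named list: `kappa`, `tss`, `jaccard`, `sorensen`, `fpb`.
#' @export
threshold_metrics <- function(c) {
  TP <- c$TP; FP <- c$FP; FN <- c$FN; TN <- c$TN
  n <- TP + FP + FN + TN
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  tss <- sens + spec - 1
  po <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kappa <- if (isTRUE(all.equal(pe, 1))) NA_real_ else (po - pe) / (1 - pe)
  jacc <- if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_
  sor <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_
  list(kappa = kappa, tss = tss, jaccard = jacc, sorensen = sor, fpb = sor)
}

#' Rank-based AUC
#'
#' The Mann-Whitney probability that a random presence outscores a random
#' background point, with ties counted one half.
#'
#' @param obs 0/1 observed labels.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\]; `NA` if either class is empty.
#' @export
auc <- function(obs, scores) {
  np <- sum(obs == 1); nb <- sum(obs == 0)
  if (np == 0 || nb == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[obs == 1]) - np * (np + 1) / 2) / (np * nb)
}

#' Continuous Boyce index
#'
#' Overlapping windows of width `window_width_fraction` of the combined
#' score range slide across the range (`n_windows` of them). Per window
#' the predicted-to-expected ratio is (fraction of presence scores in the
#' window) / (fraction of background scores in the window); windows with
#' zero expected fraction are dropped. The index is the Spearman rank
#' correlation between the P/E ratios and the window midpoints.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @param n_windows number of windows (default 101).
#' @param window_width_fraction window width as a fraction of the score
#'   range (default 0.1).
#' @return Spearman correlation in \[-1, 1\]; `NA` when fewer than 3
#'   windows have nonzero expected fraction or the range is degenerate.
#' @export
boyce <- function(presence_scores, background_scores,
                  n_windows = 101, window_width_fraction = 0.1) {
  rng <- range(c(presence_scores, background_scores))
  if (diff(rng) == 0) return(NA_real_)
  width <- window_width_fraction * diff(rng)
  lowers <- seq(rng[1], rng[2] - width, length.out = n_windows)
  P <- vapply(lowers, function(l)
    mean(presence_scores >= l & presence_scores <= l + width), 0)
  E <- vapply(lowers, function(l)
    mean(background_scores >= l & background_scores <= l + width), 0)
  ok <- E > 0
  if (sum(ok) < 3) return(NA_real_)
  mid <- lowers + width / 2
  suppressWarnings(stats::cor(P[ok] / E[ok], mid[ok], method = "spearman"))
}

#' Maximum-sensitivity-plus-specificity threshold
#'
#' Scans the unique observed scores as candidate thresholds and returns
#' the one maximizing sensitivity + specificity (prediction rule
#' `score >= threshold`); ties break to the smallest threshold. The result
#' is equivariant under strictly increasing transforms of the scores.
#'
#' @param obs 0/1 observed labels.
#' @param scores numeric scores.
#' @return The MTSS threshold (one of the observed scores).
#' @export
mtss_threshold <- function(obs, scores) {
  cand <- sort(unique(scores))
  if (length(cand) == 1) {
    warning("all scores identical; MTSS threshold is degenerate")
    return(cand)
  }
  np <- sum(obs == 1); nb <- sum(obs == 0)
  ss <- vapply(cand, function(t) {
    sum(scores >= t & obs == 1) / np + sum(scores < t & obs == 0) / nb
  }, 0)
  cand[which.max(ss)]   # which.max returns the first (smallest) maximizer
}

#' Full evaluation report for one model's scores
#'
#' Computes the seven presence-background metrics (AUC, Kappa, TSS,
#' Jaccard, Sorensen, Fpb, Boyce) plus the MTSS threshold. The
#' threshold-dependent metrics are evaluated at `threshold`, which
#' defaults to the MTSS of the supplied scores themselves.
#'
#' @param obs 0/1 observed labels.
#' @param scores numeric scores.
#' @param threshold decision threshold; `NULL` uses [mtss_threshold()].
#' @return Named list (`auc`, `kappa`, `tss`, `jaccard`, `sorensen`,
#'   `fpb`, `boyce`, `mtss_threshold`).
#' @export
evaluate_scores <- function(obs, scores, threshold = NULL) {
  if (is.null(threshold)) threshold <- mtss_threshold(obs, scores)
  tm <- threshold_metrics(confusion(obs, scores, threshold))
  c(list(auc = auc(obs, scores)), tm,
    list(boyce = boyce(scores[obs == 1], scores[obs == 0]),
         mtss_threshold = threshold))
}

#' Permutation variable importance
#'
#' For each conceptual predictor: the mean AUC drop over `n_reps`
#' permutations of its column(s) in the evaluation table (indicator
#' columns of a categorical predictor are permuted jointly with one
#' shared permutation). Negative drops are clipped to 0 and the vector is
#' normalized to sum to 1 per model. For an ensemble, the procedure runs
#' per member and a mean column across algorithms is appended.
#'
#' @param model a `member_model` or `ensemble_model`.
#' @param eval_table a training-table-shaped data.frame with `response`.
#' @param n_reps permutations per variable (default 5).
#' @param seed integer seed.
#' @return data.frame with one row per variable: `variable`, one column
#'   per algorithm, and `mean` for ensembles.
#' @export
variable_importance <- function(model, eval_table, n_reps = 5, seed = 1) {
  members <- if (inherits(model, "ensemble_model")) model$members else
    stats::setNames(list(model), model$algorithm_id)
  groups <- attr(eval_table, "groups")
  concepts <- attr(eval_table, "predictor_names")
  if (is.null(concepts))
    concepts <- setdiff(names(eval_table), "response")
  cols_of <- function(v) if (!is.null(groups[[v]])) groups[[v]] else v
  concepts <- concepts[vapply(concepts, function(v)
    all(cols_of(v) %in% names(eval_table)), TRUE)]
  obs <- eval_table$response
  out <- data.frame(variable = concepts)
  for (alg in names(members)) {
    m <- members[[alg]]
    base_auc <- auc(obs, predict_scores(m, eval_table))
    set.seed(derive_seed(seed, match(alg, names(members))))
    drops <- vapply(concepts, function(v) {
      mean(vapply(seq_len(n_reps), function(r) {
        perm <- sample(nrow(eval_table))
        tbl <- eval_table
        tbl[cols_of(v)] <- tbl[perm, cols_of(v), drop = FALSE]
        base_auc - auc(obs, predict_scores(m, tbl))
      }, 0))
    }, 0)
    drops <- pmax(drops, 0)
    out[[alg]] <- if (sum(drops) > 0) drops / sum(drops) else drops
  }
  if (length(members) > 1) out$mean <- rowMeans(out[names(members)])
  rownames(out) <- NULL
  out
}

#' Response curve by the evaluation-strip method
#'
#' Varies one continuous predictor over its observed range in `n_steps`
#' equal steps while holding every other column at its median, and records
#' the model's mean predicted suitability at each step.
#'
#' @param model a `member_model` or `ensemble_model`.
#' @param variable name of the (continuous) predictor column.
#' @param table reference data supplying the observed range and the
#'   medians (a training table).
#' @param n_steps grid resolution (default 100).
#' @param threshold optional suitability threshold; when given, the
#'   interval where the curve is `>= threshold` is reported.
#' @param smooth_window width (in steps) of the running mean applied
#'   before locating the peak; tree-based members produce piecewise-
#'   constant curves whose raw argmax is dominated by plateau edges, so
#'   the peak is read off a lightly smoothed copy (default 5). The
#'   returned curve itself is unsmoothed. Set to 1 for the raw argmax.
#' @return data.frame (`value`, `suitability`) with attributes `argmax`
#'   (value of maximum suitability) and, if `threshold` given,
#'   `above_threshold` (range of values where the curve clears it).
#' @export
response_curve <- function(model, variable, table, n_steps = 100,
                           threshold = NULL, smooth_window = 5) {
  stopifnot(variable %in% names(table))
  grid_vals <- seq(min(table[[variable]]), max(table[[variable]]), length.out = n_steps)
  strip <- table[rep(1, n_steps), setdiff(names(table), "response"), drop = FALSE]
  for (nm in names(strip)) strip[[nm]] <- stats::median(table[[nm]])
  strip[[variable]] <- grid_vals
  suit <- predict_scores(model, strip)
  out <- data.frame(value = grid_vals, suitability = suit)
  peak_on <- if (smooth_window > 1) {
    sm <- stats::filter(suit, rep(1 / smooth_window, smooth_window), sides = 2)
    ifelse(is.na(sm), -Inf, as.numeric(sm))
  } else suit
  attr(out, "argmax") <- grid_vals[which.max(peak_on)]
  if (!is.null(threshold)) {
    above <- grid_vals[suit >= threshold]
    attr(out, "above_threshold") <- if (length(above)) range(above) else NULL
  }
  out
}
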