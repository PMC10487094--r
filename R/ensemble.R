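# Six-member SDM ensemble with TSS-weighted averaging. Members are
# probabilistic presence-background learners behind one interface:
#   BRT gradient-boosted trees (xgboost), GAM spline logistic (mgcv),
#   GLM linear+quadratic logistic (stats), MXD maxent-style penalized
#   logistic on hinge+quadratic features (glmnet), RDF probability random
#   forest (ranger), SVM radial-kernel margin classifier with probability
#   calibration (e1071).

ALGORITHMS <- c("BRT", "GAM", "GLM", "MXD", "RDF", "SVM")

predictor_cols <- function(table) setdiff(names(table), "response")

is_binary_col <- function(v) all(v %in% c(0, 1))

# maxent-style features: per continuous column x, x^2 and forward/reverse
# hinges at the interior quartiles; indicator columns pass through
mxd_features <- function(df, spec = NULL) {
  if (is.null(spec)) {
    spec <- lapply(df, function(v) {
      if (is_binary_col(v)) NULL else
        stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    })
  }
  out <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    out[[nm]] <- v
    kn <- spec[[nm]]
    if (!is.null(kn)) {
      out[[paste0(nm, "_sq")]] <- v^2
      for (k in seq_along(kn)) {
        out[[paste0(nm, "_hf", k)]] <- pmax(0, v - kn[k])
        out[[paste0(nm, "_hr", k)]] <- pmax(0, kn[k] - v)
      }
    }
  }
  list(x = do.call(cbind, out), spec = spec)
}

#' Fit one ensemble member
#'
#' Fits a seeded probabilistic binary learner of the requested family on a
#' presence-background training table. Predictions from every family lie
#' in \[0, 1\]. Families: `GLM` logistic regression with linear and
#' quadratic terms; `GAM` per-predictor spline logistic regression;
#' `MXD` lasso-penalized logistic on hinge + quadratic features
#' (maxent-style); `RDF` probability random forest; `BRT` boosted trees;
#' `SVM` radial-kernel SVM with Platt probability calibration.
#'
#' @param algorithm_id one of `"BRT"`, `"GAM"`, `"GLM"`, `"MXD"`, `"RDF"`,
#'   `"SVM"`.
#' @param train training table with a 0/1 `response` column and both
#'   classes present.
#' @param seed integer seed; refitting with the same seed reproduces the
#'   predictions exactly.
#' @return Object of class `member_model`.
#' @export
fit_member <- function(algorithm_id, train, seed = 1) {
  algorithm_id <- match.arg(algorithm_id, ALGORITHMS)
  if (length(unique(train$response)) < 2)
    stop("training data contains a single class; cannot fit ", algorithm_id)
  cols <- predictor_cols(train)
  X <- as.matrix(train[cols])
  y <- train$response
  set.seed(seed)
  fit <- switch(algorithm_id,
    GLM = {
      terms <- unlist(lapply(cols, function(nm)
        if (is_binary_col(train[[nm]])) nm else c(nm, sprintf("I(%s^2)", nm))))
      f <- stats::reformulate(terms, response = "response")
      suppressWarnings(stats::glm(f, data = train, family = stats::binomial()))
    },
    GAM = {
      terms <- vapply(cols, function(nm) {
        nu <- length(unique(train[[nm]]))
        if (is_binary_col(train[[nm]]) || nu < 8) nm
        else sprintf("s(%s, k = %d)", nm, min(8L, nu - 1L))
      }, "")
      f <- stats::reformulate(terms, response = "response")
      suppressWarnings(mgcv::gam(f, data = train, family = stats::binomial(),
                                 method = "REML"))
    },
    MXD = {
      feats <- mxd_features(train[cols])
      if (nrow(train) >= 30) {
        foldid <- sample(rep_len(1:5, nrow(train)))
        cv <- glmnet::cv.glmnet(feats$x, y, family = "binomial", alpha = 1,
                                foldid = foldid)
        list(fit = cv$glmnet.fit, lambda = cv$lambda.min, spec = feats$spec)
      } else {
        g <- glmnet::glmnet(feats$x, y, family = "binomial", alpha = 1)
        list(fit = g, lambda = min(g$lambda), spec = feats$spec)
      }
    },
    RDF = ranger::ranger(x = train[cols], y = factor(y, levels = c(0, 1)),
                         probability = TRUE, num.trees = 500, seed = seed),
    BRT = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    subsample = 0.8, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = 150, verbose = 0),
    SVM = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = "radial", probability = TRUE, scale = TRUE)
  )
  structure(list(algorithm_id = algorithm_id, fit = fit,
                 predictor_names = cols, seed = seed),
            class = "member_model")
}

#' Predict suitability scores
#'
#' Dispatches on `member_model` / `ensemble_model` and returns per-row
#' probabilities in \[0, 1\].
#'
#' @param model fitted model object.
#' @param newdata data.frame holding the model's predictor columns.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, newdata) UseMethod("predict_scores")

#' @export
predict_scores.member_model <- function(model, newdata) {
  df <- newdata[model$predictor_names]
  X <- as.matrix(df)
  p <- switch(model$algorithm_id,
    GLM = stats::predict(model$fit, newdata = df, type = "response"),
    GAM = as.numeric(mgcv::predict.gam(model$fit, newdata = df, type = "response")),
    MXD = {
      fx <- mxd_features(df, model$fit$spec)$x
      as.numeric(stats::predict(model$fit$fit, newx = fx, s = model$fit$lambda,
                                type = "response"))
    },
    RDF = stats::predict(model$fit, data = df)$predictions[, "1"],
    BRT = stats::predict(model$fit, newdata = xgboost::xgb.DMatrix(X, nthread = 1)),
    SVM = {
      pr <- stats::predict(model$fit, newdata = X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
predict_scores.ensemble_model <- function(model, newdata) {
  p <- vapply(names(model$weights),
              function(a) predict_scores(model$members[[a]], newdata),
              numeric(nrow(newdata)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  as.numeric(p %*% model$weights)
}

#' TSS-proportional ensemble weights
#'
#' Weights each member by its TSS: `W_j = r_j / sum(r_j)`. Members with
#' TSS `<= 0` carry no information under this scheme and are excluded
#' with a warning before normalization; if no member has positive TSS the
#' call fails.
#'
#' @param tss_values named numeric vector of member TSS values.
#' @return Named weight vector summing to 1 over the retained members
#'   (excluded members are absent).
#' @export
ensemble_weights <- function(tss_values) {
  bad <- tss_values <= 0
  if (all(bad)) stop("no member has positive TSS; cannot form ensemble weights")
  if (any(bad))
    warning("excluding member(s) with non-positive TSS: ",
            paste(names(tss_values)[bad], collapse = ", "))
  w <- tss_values[!bad]
  w / sum(w)
}

#' Weighted-mean ensemble prediction over a stack
#'
#' Computes the cellwise TSS-weighted mean of the member suitability maps.
#' Output values lie within the cellwise min/max of the member maps;
#' nodata in any predictor layer propagates.
#'
#' @param ensemble an `ensemble_model`.
#' @param stack named list of `hs_raster` predictor layers.
#' @return Continuous `hs_raster` of ensemble suitability.
#' @export
ensemble_predict <- function(ensemble, stack) {
  pf <- stack_prediction_frame(stack, ensemble$table_template)
  scores <- predict_scores(ensemble, pf$data)
  v <- matrix(NA_real_, pf$grid$n_rows, pf$grid$n_cols)
  v[pf$cell_index] <- scores
  make_raster(pf$grid, v, pf$mask, kind = "continuous")
}

#' Fit the TSS-weighted ensemble over repeated splits
#'
#' For each of `n_runs` runs and each algorithm: split the table 80/20
#' (stratified), fit on the training part, take the MTSS threshold from
#' the training scores, and evaluate the seven metrics on the held-out
#' part. Per-algorithm TSS is averaged over runs, the ensemble weights are
#' the TSS-proportional weights of those means, and the final members are
#' refit on the full table. The per-run reports are retained for
#' summary tables.
#'
#' @param table training table from [build_training_table()].
#' @param algorithms algorithm subset (default all six).
#' @param n_runs number of evaluation splits (default 10).
#' @param master_seed master seed; every split and fit derives from it.
#' @param train_fraction training fraction per split (default 0.8).
#' @return Object of class `ensemble_model`: `members` (refit on all
#'   data), `weights`, `mean_tss`, `reports` (one row per run x
#'   algorithm), `ensemble_auc` (mean held-out AUC of the weighted
#'   ensemble across the runs), `mtss_threshold` (of the ensemble scores
#'   on the full table) and the table template for prediction encoding.
#' @export
fit_ensemble <- function(table, algorithms = ALGORITHMS, n_runs = 10,
                         master_seed = 1, train_fraction = 0.8) {
  reports <- list()
  test_scores <- list()   # per run: obs + per-algorithm held-out predictions
  for (run in seq_len(n_runs)) {
    parts <- split_train_test(table, fraction = train_fraction,
                              run_id = run, seed = master_seed)
    run_scores <- list(obs = parts$test$response)
    for (alg in algorithms) {
      m <- fit_member(alg, parts$train, seed = derive_seed(master_seed, 100 * run))
      thr <- mtss_threshold(parts$train$response,
                            predict_scores(m, parts$train))
      p_test <- predict_scores(m, parts$test)
      run_scores[[alg]] <- p_test
      ev <- evaluate_scores(parts$test$response, p_test, threshold = thr)
      reports[[length(reports) + 1]] <-
        data.frame(run = run, algorithm = alg, auc = ev$auc, kappa = ev$kappa,
                   tss = ev$tss, jaccard = ev$jaccard, sorensen = ev$sorensen,
                   fpb = ev$fpb, boyce = ev$boyce, mtss_threshold = thr)
    }
    test_scores[[run]] <- run_scores
  }
  reports <- do.call(rbind, reports)
  mean_tss <- tapply(reports$tss, reports$algorithm, mean)[algorithms]
  weights <- ensemble_weights(mean_tss)
  # held-out skill of the weighted ensemble itself: combine each run's
  # test-fold member predictions with the final weights
  ensemble_auc <- mean(vapply(test_scores, function(rs) {
    p <- vapply(names(weights), function(a) rs[[a]], numeric(length(rs$obs)))
    auc(rs$obs, as.numeric(p %*% weights))
  }, 0))
  members <- lapply(stats::setNames(nm = names(weights)), function(alg)
    fit_member(alg, table, seed = derive_seed(master_seed, 0)))
  ens <- structure(list(members = members, weights = weights,
                        mean_tss = mean_tss, reports = reports,
                        ensemble_auc = ensemble_auc,
                        table_template = table),
                   class = "ensemble_model")
  ens$mtss_threshold <- mtss_threshold(table$response, predict_scores(ens, table))
  ens
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>", length(x$members), "members\n")
  print(round(rbind(mean_tss = x$mean_tss[names(x$weights)], weight = x$weights), 3))
  cat("ensemble MTSS threshold:", round(x$mtss_threshold, 3), "\n")
  invisible(x)
}

#' Table-2-style evaluation summary
#'
#' Mean of each metric over the stored per-run reports, one row per
#' algorithm.
#'
#' @param ensemble an `ensemble_model`.
#' @return data.frame with columns `algorithm`, `auc`, `kappa`, `tss`,
#'   `jaccard`, `sorensen`, `fpb`, `boyce`.
#' @export
evaluation_summary <- function(ensemble) {
  rep <- ensemble$reports
  metrics <- c("auc", "kappa", "tss", "jaccard", "sorensen", "fpb", "boyce")
  agg <- stats::aggregate(rep[metrics], by = list(algorithm = rep$algorithm),
                          FUN = mean, na.rm = TRUE)
  agg[match(intersect(ALGORITHMS, agg$algorithm), agg$algorithm), ]
}
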