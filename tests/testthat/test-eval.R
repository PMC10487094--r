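test_that("confusion counts follow the >= threshold rule", {
  obs <- c(1, 1, 0, 0)
  sc <- c(0.8, 0.9, 0.1, 0.2)
  c0 <- confusion(obs, sc, 0)
  expect_equal(c0$FN, 0); expect_equal(c0$TP, 2); expect_equal(c0$FP, 2)
  chi <- confusion(obs, sc, 0.95)
  expect_equal(chi$TP, 0); expect_equal(chi$TN, 2)
  cmid <- confusion(obs, sc, 0.5)
  expect_equal(unlist(cmid[c("TP", "TN", "FP", "FN")]), c(TP = 2, TN = 2, FP = 0, FN = 0))
  # boundary: a score exactly at the threshold predicts presence
  expect_equal(confusion(1, 0.5, 0.5)$TP, 1)
})

test_that("threshold metrics match hand arithmetic", {
  perfect <- threshold_metrics(confusion(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2), 0.5))
  expect_equal(unlist(perfect), c(kappa = 1, tss = 1, jaccard = 1, sorensen = 1, fpb = 1))

  m <- threshold_metrics(structure(list(TP = 40, FP = 10, FN = 10, TN = 40),
                                   class = "confusion_counts"))
  expect_equal(m$tss, 0.6)
  expect_equal(m$kappa, 0.6)
  expect_equal(m$jaccard, 40 / 60)
  expect_equal(m$sorensen, 0.8)
  expect_equal(m$fpb, 0.8)

  chance <- threshold_metrics(structure(list(TP = 25, FP = 25, FN = 25, TN = 25),
                                        class = "confusion_counts"))
  expect_equal(chance$tss, 0); expect_equal(chance$kappa, 0)

  empty <- threshold_metrics(structure(list(TP = 0, FP = 0, FN = 0, TN = 50),
                                       class = "confusion_counts"))
  expect_true(is.na(empty$tss))
  expect_true(is.na(empty$jaccard))
})

test_that("jaccard and sorensen satisfy S = 2J/(1+J) exactly", {
  set.seed(2)
  for (i in 1:20) {
    cc <- structure(as.list(stats::setNames(sample(1:50, 4, replace = TRUE),
                                            c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
    m <- threshold_metrics(cc)
    expect_lte(m$jaccard, m$sorensen)
    expect_equal(m$sorensen, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
  }
})

test_that("rank AUC equals brute-force pair enumeration", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    obs <- rbinom(n, 1, 0.5)
    if (length(unique(obs)) < 2) next
    sc <- round(runif(n), 2)   # rounding forces ties
    expect_equal(auc(obs, sc), auc_bruteforce(obs, sc))
  }
})

test_that("rank AUC agrees with an independent implementation", {
  set.seed(5)
  obs <- rbinom(150, 1, 0.4)
  sc <- runif(150) + 0.3 * obs
  expect_equal(auc(obs, sc),
               as.numeric(pROC::auc(pROC::roc(obs, sc, quiet = TRUE))))
})

test_that("Boyce index tracks calibration and flips sign with the scores", {
  # monotone case: presence density rises as x^3 against a uniform
  # background, so P/E increases across the score range
  n <- 2000
  pres <- seq(0.5 / n, 1 - 0.5 / n, length.out = n)^(1 / 4)
  bg <- seq(0.5 / n, 1 - 0.5 / n, length.out = n)
  b <- boyce(pres, bg)
  # independent oracle: recompute windows and Spearman directly
  rng <- range(c(pres, bg)); w <- 0.1 * diff(rng)
  lowers <- seq(rng[1], rng[2] - w, length.out = 101)
  P <- sapply(lowers, function(l) mean(pres >= l & pres <= l + w))
  E <- sapply(lowers, function(l) mean(bg >= l & bg <= l + w))
  keep <- E > 0
  oracle <- cor(P[keep] / E[keep], (lowers + w / 2)[keep], method = "spearman")
  expect_equal(b, oracle)
  expect_gt(b, 0.99)

  expect_equal(boyce(-pres, -bg), -b)

  # same distribution: index near zero (seed-fixed)
  set.seed(9)
  expect_lt(abs(boyce(runif(2000), runif(2000))), 0.3)
  expect_true(is.na(boyce(rep(0.5, 5), rep(0.5, 7))))
})

test_that("Boyce is centred near zero under the null across many seeds", {
  vals <- vapply(1:60, function(s) {
    set.seed(s)
    boyce(runif(400), runif(400))
  }, 0)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("MTSS equals the exhaustive scan and maps through monotone transforms", {
  obs <- c(1, 1, 0, 0)
  sc <- c(0.8, 0.9, 0.1, 0.2)
  expect_equal(mtss_threshold(obs, sc), 0.8)
  set.seed(13)
  for (i in 1:15) {
    n <- sample(8:120, 1)
    o <- rbinom(n, 1, 0.5)
    if (length(unique(o)) < 2) next
    s <- round(runif(n), 2)
    expect_equal(mtss_threshold(o, s), mtss_bruteforce(o, s))
    # strictly monotone transform: threshold maps through it
    expect_equal(mtss_threshold(o, s^2), mtss_threshold(o, s)^2)
  }
  expect_warning(t0 <- mtss_threshold(c(1, 0), c(0.4, 0.4)), "degenerate")
  expect_equal(t0, 0.4)
})

test_that("evaluate_scores bundles all seven metrics coherently", {
  set.seed(21)
  obs <- rep(c(1, 0), each = 100)
  sc <- plogis(rnorm(200, mean = 1.5 * obs))
  ev <- evaluate_scores(obs, sc)
  expect_named(ev, c("auc", "kappa", "tss", "jaccard", "sorensen", "fpb",
                     "boyce", "mtss_threshold"))
  # tss at the reported threshold reproduces from the confusion counts
  m <- threshold_metrics(confusion(obs, sc, ev$mtss_threshold))
  expect_equal(ev$tss, m$tss)
  expect_true(ev$jaccard <= ev$sorensen)
  expect_true(all(unlist(ev[c("auc", "jaccard", "sorensen", "fpb")]) >= 0 &
                    unlist(ev[c("auc", "jaccard", "sorensen", "fpb")]) <= 1))
})

test_that("permutation importance separates used from unused predictors", {
  set.seed(31)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)   # x2 unused by the truth
  y <- rbinom(n, 1, plogis(2.5 * x1))
  tab <- structure(data.frame(x1 = x1, x2 = x2, response = y),
                   predictor_names = c("x1", "x2"))
  m <- fit_member("GLM", tab, seed = 1)
  vi <- variable_importance(m, tab, n_reps = 5, seed = 2)
  expect_gt(vi$GLM[vi$variable == "x1"], 0.9)
  expect_lt(vi$GLM[vi$variable == "x2"], 0.1)
  expect_equal(sum(vi$GLM), 1)
})

test_that("response curves are flat for ignored variables and bounded", {
  set.seed(41)
  n <- 300
  # x2 is constant at fit time, so the model cannot use it: exact flatness
  tab <- structure(data.frame(x1 = rnorm(n), x2 = rep(0.37, n)),
                   predictor_names = c("x1", "x2"))
  tab$response <- rbinom(n, 1, plogis(2 * tab$x1))
  m <- suppressWarnings(fit_member("GLM", tab, seed = 1))
  strip <- tab
  strip$x2 <- seq(-2, 2, length.out = n)   # give the strip a range to sweep
  rc2 <- suppressWarnings(response_curve(m, "x2", strip))
  expect_lt(diff(range(rc2$suitability)), 1e-8)
  rc1 <- suppressWarnings(response_curve(m, "x1", tab))
  expect_true(all(rc1$suitability >= 0 & rc1$suitability <= 1))
  # the informative variable sweeps a wide suitability range
  expect_gt(diff(range(rc1$suitability)), 0.5)
})
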