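test_that("binarization calls presence at and above the cutoff", {
  expect_identical(binarize(c(0.3, 0.6), 0.5), c(0L, 1L))
  expect_identical(binarize(c(0.5, 0.49999), 0.5), c(1L, 0L))
  expect_identical(binarize(c(0.2, 0.8), 0), c(1L, 1L))
  expect_error(binarize(c(-0.1, 0.5), 0.5), "\\[0, 1\\]")
})

test_that("confusion matrices tally the four outcomes", {
  m <- confusion(c(1, 0), c(1, 0))
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(1, 1, 0, 0))
  m2 <- confusion(c(1, 1), c(0, 0))
  expect_equal(m2$FP, 2)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "differ")
})

test_that("Cohen's kappa reproduces worked confusion-matrix examples", {
  # median-fold matrix of the best observed-co-predictor model:
  # predicted absence (36, 0), predicted presence (4, 13), n = 53
  m <- confusion(c(rep(1, 17), rep(0, 36)),
                 c(rep(1, 13), rep(0, 4), rep(0, 36)))
  expect_equal(m$n, 53)
  expect_equal(round(cohen_kappa(m)$k, 3), 0.815)

  # two-co-predictor cascade matrix (36, 1; 4, 12): direct evaluation of
  # the chance-corrected formula gives 16.151/21.151
  m8 <- structure(list(TP = 12, FP = 4, FN = 1, TN = 36, n = 53),
                  class = "confusion_matrix")
  chance <- ((12 + 1) * (12 + 4) + (4 + 36) * (1 + 36)) / 53
  expect_equal(cohen_kappa(m8)$k, (48 - chance) / (53 - chance))
  expect_equal(round(cohen_kappa(m8)$k, 4), 0.7636)

  perfect <- structure(list(TP = 10, FP = 0, FN = 0, TN = 10, n = 20),
                       class = "confusion_matrix")
  expect_equal(cohen_kappa(perfect)$k, 1)

  allpos <- structure(list(TP = 5, FP = 5, FN = 0, TN = 0, n = 10),
                      class = "confusion_matrix")
  expect_equal(cohen_kappa(allpos)$k, 0)

  degen <- structure(list(TP = 10, FP = 0, FN = 0, TN = 0, n = 10),
                     class = "confusion_matrix")
  expect_error(cohen_kappa(degen), "degenerate agreement")
})

test_that("kappa equals the (po - pe)/(1 - pe) form on random matrices", {
  set.seed(42)
  for (i in 1:300) {
    m <- random_confusion()
    po <- (m$TP + m$TN) / m$n
    pe <- ((m$TP + m$FN) * (m$TP + m$FP) +
             (m$FP + m$TN) * (m$FN + m$TN)) / m$n^2
    expect_equal(cohen_kappa(m)$k, (po - pe) / (1 - pe))
    # simultaneous class-label swap leaves kappa unchanged
    sw <- structure(list(TP = m$TN, FP = m$FN, FN = m$FP, TN = m$TP,
                         n = m$n), class = "confusion_matrix")
    expect_equal(cohen_kappa(sw)$k, cohen_kappa(m)$k)
  }
})

test_that("kappa confidence intervals behave like a 1/sqrt(n) bound", {
  perfect <- structure(list(TP = 10, FP = 0, FN = 0, TN = 10, n = 20),
                       class = "confusion_matrix")
  expect_equal(unname(kappa_ci(perfect)), c(1, 1))

  set.seed(17)
  for (i in 1:50) {
    m <- random_confusion()
    ci <- kappa_ci(m)
    k <- cohen_kappa(m)$k
    expect_lte(ci[["low"]], k)
    expect_gte(ci[["high"]], k)
  }

  m <- structure(list(TP = 13, FP = 4, FN = 6, TN = 30, n = 53),
                 class = "confusion_matrix")
  m4 <- structure(list(TP = 52, FP = 16, FN = 24, TN = 120, n = 212),
                  class = "confusion_matrix")
  w1 <- diff(unname(kappa_ci(m)))
  w4 <- diff(unname(kappa_ci(m4)))
  expect_equal(w4 / w1, 0.5, tolerance = 1e-10)
})

test_that("agreement bands follow the conventional scale", {
  expect_equal(landis_koch(-0.2), "poor")
  expect_equal(landis_koch(0), "poor")
  expect_equal(landis_koch(0.15), "slight")
  expect_equal(landis_koch(0.35), "fair")
  expect_equal(landis_koch(0.45), "moderate")
  expect_equal(landis_koch(0.627), "substantial")
  expect_equal(landis_koch(0.8), "substantial")   # boundary is inclusive
  expect_equal(landis_koch(0.815), "almost perfect")
  expect_equal(landis_koch(0.627, alias = TRUE), "good")
  expect_equal(landis_koch(0.815, alias = TRUE), "very good")
  expect_error(landis_koch(1.2), "\\[-1, 1\\]")
})

test_that("ROC analysis finds the Youden-optimal midpoint cutoff", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$best_cutoff, 0.5)

  flat <- roc_analysis(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$best_cutoff, 0.5)

  expect_error(roc_analysis(c(0.2, 0.4), c(1, 1)), "single class")

  set.seed(91)
  for (i in 1:20) {
    n <- 150
    scores <- round(runif(n), 2)  # rounding forces ties
    obs <- rbinom(n, 1, plogis(3 * (scores - 0.5)))
    if (length(unique(obs)) < 2) next
    r <- roc_analysis(scores, obs)
    expect_equal(r$auc, oracle_auc_mw(scores, obs), tolerance = 1e-10)
    o <- oracle_best_cutoff(scores, obs)
    expect_equal(r$best_cutoff, o$cutoff)
    expect_equal(r$best_j, o$j, tolerance = 1e-12)
    # monotone curve invariant
    expect_true(all(diff(r$sensitivities) <= 1e-12))
    expect_true(all(diff(r$specificities) >= -1e-12))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(120)
  obs <- rbinom(120, 1, scores)
  ref <- suppressMessages(pROC::auc(pROC::roc(obs, scores, quiet = TRUE)))
  expect_equal(roc_analysis(scores, obs)$auc, as.numeric(ref),
               tolerance = 1e-10)
})

test_that("cross-validation summarizes per-fold agreement", {
  data <- env_driven_survey(n = 100)
  # a stub factory that predicts the observed occurrence (near-)perfectly
  perfect_factory <- function(train_data, target, seed) {
    list(predict = function(nd) 0.8 * nd$occurrence[, target] + 0.1)
  }
  cv <- cross_validate(data, "tgt", perfect_factory, k = 5, seed = 2)
  expect_equal(cv$kappas, rep(1, 5))
  expect_equal(cv$median_k, 1)
  expect_s3_class(cv$median_fold_matrix, "confusion_matrix")

  constant_factory <- function(train_data, target, seed) {
    list(predict = function(nd) rep(0.5, length(nd$site_ids)))
  }
  cv0 <- cross_validate(data, "tgt", constant_factory, k = 5, seed = 2)
  expect_equal(cv0$median_k, 0)

  cv_a <- cross_validate(data, "tgt", perfect_factory, k = 5, seed = 9)
  cv_b <- cross_validate(data, "tgt", perfect_factory, k = 5, seed = 9)
  expect_identical(cv_a$folds, cv_b$folds)
})
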