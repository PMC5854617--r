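#' Binarize probability scores at a cutoff
#'
#' Scores greater than or equal to the cutoff are called presences; the tie
#' at the cutoff counts as presence by convention.
#'
#' @param scores probabilities in \[0, 1\].
#' @param cutoff decision threshold.
#' @return Integer vector of 0/1 calls.
#' @export
binarize <- function(scores, cutoff) {
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  as.integer(scores >= cutoff)
}

#' Confusion matrix of binary predictions against observations
#'
#' @param pred,obs binary vectors of equal, positive length.
#' @return An object of class `confusion_matrix` with counts `TP`, `FP`,
#'   `FN`, `TN` and total `n`.
#' @export
confusion <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs lengths differ (", length(pred), " vs ",
         length(obs), ")", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty vectors (n = 0)", call. = FALSE)
  if (!is_binary_vector(pred) || !is_binary_vector(obs)) {
    stop("pred and obs must be binary 0/1", call. = FALSE)
  }
  structure(list(TP = sum(pred == 1 & obs == 1),
                 FP = sum(pred == 1 & obs == 0),
                 FN = sum(pred == 0 & obs == 1),
                 TN = sum(pred == 0 & obs == 0),
                 n = length(pred)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FN, x$FP, x$TP), 2, 2,
              dimnames = list(predicted = c("absence", "presence"),
                              observed = c("absence", "presence")))
  print(m)
  invisible(x)
}

kappa_chance_term <- function(m) {
  ((m$TP + m$FN) * (m$TP + m$FP) + (m$FP + m$TN) * (m$FN + m$TN)) / m$n
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement between predictions and observations,
#'
#' \deqn{k = \frac{(TP+TN) - [((TP+FN)(TP+FP)+(FP+TN)(FN+TN))/n]}
#'                {n - [((TP+FN)(TP+FP)+(FP+TN)(FN+TN))/n]}}
#'
#' i.e. the deviation of the model's agreement from that of a random
#' process with the same margins.
#'
#' @param m a [confusion()] matrix.
#' @return An object of class `kappa_result` with elements `k` and `label`
#'   (the Landis-Koch band of `k`).
#' @export
cohen_kappa <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  chance <- kappa_chance_term(m)
  denom <- m$n - chance
  if (abs(denom) < 1e-12) {
    stop("degenerate agreement: chance term equals n (both margins ",
         "single-class)", call. = FALSE)
  }
  k <- ((m$TP + m$TN) - chance) / denom
  structure(list(k = k, label = landis_koch(max(-1, min(1, k)))),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s)\n", x$k, x$label))
  invisible(x)
}

#' Confidence interval for Cohen's kappa
#'
#' Normal-approximation interval `k +/- z * SE` with the large-sample
#' standard error `sqrt(po (1 - po) / (n (1 - pe)^2))`, clipped to
#' \[-1, 1\].
#'
#' @param m a [confusion()] matrix.
#' @param alpha two-sided error rate (default 0.05).
#' @return Numeric vector `c(low, high)`.
#' @export
kappa_ci <- function(m, alpha = 0.05) {
  k <- cohen_kappa(m)$k
  po <- (m$TP + m$TN) / m$n
  pe <- kappa_chance_term(m) / m$n
  se <- sqrt(po * (1 - po) / (m$n * (1 - pe)^2))
  z <- stats::qnorm(1 - alpha / 2)
  c(low = max(-1, k - z * se), high = min(1, k + z * se))
}

#' Landis-Koch agreement category of a kappa value
#'
#' Bands: `<= 0` poor, `(0, 0.2]` slight, `(0.2, 0.4]` fair, `(0.4, 0.6]`
#' moderate, `(0.6, 0.8]` substantial, `(0.8, 1]` almost perfect. With
#' `alias = TRUE` the top two bands are reported with the informal labels
#' "good" and "very good" often used in the SDM literature.
#'
#' @param k kappa value in \[-1, 1\].
#' @param alias report the top two bands as "good" / "very good".
#' @return Character label.
#' @export
landis_koch <- function(k, alias = FALSE) {
  if (!is.finite(k) || k < -1 || k > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  label <- if (k <= 0) "poor"
  else if (k <= 0.2) "slight"
  else if (k <= 0.4) "fair"
  else if (k <= 0.6) "moderate"
  else if (k <= 0.8) "substantial"
  else "almost perfect"
  if (alias) {
    if (label == "substantial") label <- "good"
    if (label == "almost perfect") label <- "very good"
  }
  label
}

#' ROC analysis and optimal binarization cutoff
#'
#' Builds the ROC curve over all distinct score thresholds (presence called
#' when `score >= threshold`), computes the area under the curve by the
#' trapezoid rule, and picks the cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1` among the midpoints between adjacent
#' distinct scores. Ties on `J` are broken toward the candidate nearest 0.5,
#' then toward the smaller cutoff. With fewer than two distinct scores the
#' cutoff falls back to 0.5.
#'
#' @param scores probabilities in \[0, 1\].
#' @param obs binary observations; both classes must be present.
#' @return An object of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `best_cutoff`, `best_j`.
#' @export
roc_analysis <- function(scores, obs) {
  if (length(scores) != length(obs)) {
    stop("scores and obs lengths differ", call. = FALSE)
  }
  if (!is_binary_vector(obs)) stop("obs must be binary 0/1", call. = FALSE)
  if (length(unique(obs)) < 2) {
    stop("degenerate ROC: obs contains a single class", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  npos <- sum(obs == 1)
  nneg <- sum(obs == 0)
  sens_spec <- function(cut) {
    pred <- scores >= cut
    c(sens = sum(pred & obs == 1) / npos,
      spec = sum(!pred & obs == 0) / nneg)
  }
  uq <- sort(unique(scores))
  thresholds <- c(uq, Inf)
  curve <- vapply(thresholds, sens_spec, numeric(2))
  sens <- curve["sens", ]
  spec <- curve["spec", ]
  fpr <- c(1, 1 - spec)  # prepend the all-presence corner
  tpr <- c(1, sens)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (length(uq) >= 2) {
    candidates <- (utils::head(uq, -1) + utils::tail(uq, -1)) / 2
    j <- vapply(candidates, function(ct) sum(sens_spec(ct)) - 1, numeric(1))
    best <- which(j > max(j) - 1e-12)
    best <- best[order(abs(candidates[best] - 0.5), candidates[best])][1]
    best_cutoff <- candidates[best]
    best_j <- j[best]
  } else {
    best_cutoff <- 0.5
    best_j <- sum(sens_spec(0.5)) - 1
  }
  structure(list(thresholds = thresholds,
                 sensitivities = sens,
                 specificities = spec,
                 auc = auc,
                 best_cutoff = best_cutoff,
                 best_j = best_j),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: auc = %.3f, best cutoff = %.3f (Youden J = %.3f)\n",
              x$auc, x$best_cutoff, x$best_j))
  invisible(x)
}

#' Stratified k-fold cross-validation of a trainable model
#'
#' For each fold the factory trains a model on the remaining folds and
#' scores the held-out sites; scores are binarized at the ROC-optimal cutoff
#' and summarized by a confusion matrix and Cohen's kappa. In the default
#' `"test"` cutoff mode the cutoff is chosen on the held-out fold's own
#' scores (the historical convention for this workflow; note it leaks the
#' held-out labels into the cutoff). The `"train"` mode picks the cutoff
#' from the training-fold scores and is the leakage-free alternative.
#'
#' @param data a [survey_dataset()].
#' @param target target species name.
#' @param factory `function(train_data, target, seed)` returning a model
#'   object whose `$predict(newdata)` yields occurrence probabilities, e.g.
#'   [species_net_factory()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds and per-fold training.
#' @param cutoff_mode `"test"` (default) or `"train"`.
#' @return An object of class `cv_report`: `folds` (data frame with per-fold
#'   TP/FP/FN/TN, kappa and cutoff), `matrices`, `kappas`, `median_k`,
#'   `median_fold`, `median_fold_matrix`, `assignment`.
#' @export
cross_validate <- function(data, target, factory, k = 5, seed = 1,
                           cutoff_mode = c("test", "train")) {
  cutoff_mode <- match.arg(cutoff_mode)
  fold <- stratified_folds(data, target, k = k, seed = seed)
  mats <- vector("list", k)
  kappas <- numeric(k)
  cutoffs <- numeric(k)
  for (i in seq_len(k)) {
    train_data <- subset_sites(data, fold != i)
    test_data <- subset_sites(data, fold == i)
    model <- factory(train_data, target, derive_seed(seed, i))
    scores_test <- model$predict(test_data)
    obs_test <- test_data$occurrence[, target]
    cutoff <- if (cutoff_mode == "test") {
      roc_analysis(scores_test, obs_test)$best_cutoff
    } else {
      roc_analysis(model$predict(train_data),
                   train_data$occurrence[, target])$best_cutoff
    }
    pred <- binarize(scores_test, cutoff)
    mats[[i]] <- confusion(pred, obs_test)
    kappas[i] <- cohen_kappa(mats[[i]])$k
    cutoffs[i] <- cutoff
  }
  med <- stats::median(kappas)
  median_fold <- which.min(abs(kappas - med))
  folds_df <- data.frame(fold = seq_len(k),
                         TP = vapply(mats, `[[`, numeric(1), "TP"),
                         FP = vapply(mats, `[[`, numeric(1), "FP"),
                         FN = vapply(mats, `[[`, numeric(1), "FN"),
                         TN = vapply(mats, `[[`, numeric(1), "TN"),
                         kappa = kappas,
                         cutoff = cutoffs)
  structure(list(folds = folds_df,
                 matrices = mats,
                 kappas = kappas,
                 median_k = med,
                 median_fold = median_fold,
                 median_fold_matrix = mats[[median_fold]],
                 assignment = fold,
                 cutoff_mode = cutoff_mode),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", nrow(x$folds), "folds, median kappa =",
      sprintf("%.3f", x$median_k), "\n")
  print(x$folds, row.names = FALSE)
  invisible(x)
}

#' Export a cross-validation report to CSV
#'
#' @param cv a [cross_validate()] report.
#' @param path output CSV path.
#' @return `cv`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  utils::write.csv(cv$folds, path, row.names = FALSE)
  invisible(cv)
}
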