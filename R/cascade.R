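# The four-step cascade workflow: environment-only baseline, co-predictor
# screening against the baseline kappa confidence interval, environment-only
# sub-models for the selected species, and assembly of a cascade that feeds
# sub-model occurrence probabilities into the target network so the final
# model consumes environmental inputs only.

# Build the input matrix for a model that uses the environmental variables
# plus (optionally) observed occurrence columns of other species.
model_inputs <- function(data, extra_species = character(0),
                         extra_cols = NULL) {
  x <- data$environment
  if (length(extra_species) > 0) {
    x <- cbind(x, data$occurrence[, extra_species, drop = FALSE])
  }
  if (!is.null(extra_cols)) x <- cbind(x, extra_cols)
  x
}

#' Model factory: environment (+ observed species) network
#'
#' Returns a factory for [cross_validate()] that trains a network on the
#' environmental variables plus, optionally, the observed occurrence of
#' `extra_inputs` species.
#'
#' @param config a [train_config()].
#' @param extra_inputs character vector of co-predictor species whose
#'   observed occurrence joins the inputs (default none).
#' @return `function(train_data, target, seed)` producing an object with a
#'   `$predict(newdata)` method.
#' @export
species_net_factory <- function(config = train_config(),
                                extra_inputs = character(0)) {
  force(config); force(extra_inputs)
  function(train_data, target, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    w <- train_network(model_inputs(train_data, extra_inputs),
                       train_data$occurrence[, target], cfg)
    list(weights = w,
         predict = function(newdata) {
           nn_forward(w, model_inputs(newdata, extra_inputs))
         })
  }
}

model_spec <- function(target, input_env, input_species, input_mode,
                       weights, cutoff, cv, config) {
  stopifnot(weights$n_inputs == length(input_env) + length(input_species))
  structure(list(target = target,
                 input_env = input_env,
                 input_species = input_species,
                 input_mode = input_mode,
                 weights = weights,
                 cutoff = cutoff,
                 cv = cv,
                 config = config),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec for '", x$target, "': ", length(x$input_env),
      " environmental inputs", sep = "")
  if (length(x$input_species)) {
    cat(" + species inputs [", paste(x$input_species, collapse = ", "),
        "] (", x$input_mode, ")", sep = "")
  }
  cat("\n  cutoff =", sprintf("%.3f", x$cutoff))
  if (!is.null(x$cv)) cat(", CV median kappa =", sprintf("%.3f", x$cv$median_k))
  cat("\n")
  invisible(x)
}

fit_final_model <- function(data, target, extra_species, config, seed,
                            input_mode = "observed", cv = NULL) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  x <- model_inputs(data, extra_species)
  y <- data$occurrence[, target]
  w <- train_network(x, y, cfg)
  cutoff <- roc_analysis(nn_forward(w, x), y)$best_cutoff
  model_spec(target = target,
             input_env = data$env_names,
             input_species = extra_species,
             input_mode = input_mode,
             weights = w, cutoff = cutoff, cv = cv, config = cfg)
}

#' Step 1: environment-only baseline model
#'
#' Trains and cross-validates a network predicting the target species from
#' the environmental variables alone, establishing the baseline performance
#' level (median CV kappa with its confidence interval) that co-predictor
#' screening must beat.
#'
#' @param data a normalized [survey_dataset()].
#' @param target target species name.
#' @param config a [train_config()].
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @param cutoff_mode see [cross_validate()].
#' @return A `model_spec` whose `cv` element holds the [cross_validate()]
#'   report; `baseline_k` and `baseline_ci` attributes carry the kappa of
#'   the median fold and its asymptotic confidence interval.
#' @export
train_baseline <- function(data, target, config = train_config(),
                           folds = 5, seed = 1,
                           cutoff_mode = c("test", "train")) {
  cutoff_mode <- match.arg(cutoff_mode)
  validate_survey(data)
  if (!data$normalized) {
    stop("data must be normalized before training (see ",
         "normalize_environment())", call. = FALSE)
  }
  if (!target %in% data$species_names) {
    stop("unknown target species: ", target, call. = FALSE)
  }
  cv <- cross_validate(data, target, species_net_factory(config),
                       k = folds, seed = seed, cutoff_mode = cutoff_mode)
  ms <- fit_final_model(data, target, character(0), config,
                        seed = derive_seed(seed, 0), cv = cv)
  attr(ms, "baseline_k") <- cohen_kappa(cv$median_fold_matrix)$k
  attr(ms, "baseline_ci") <- kappa_ci(cv$median_fold_matrix)
  ms
}

#' Step 2: screen candidate co-predictor species
#'
#' For each candidate, a network with the candidate's observed occurrence as
#' one extra input is cross-validated; a candidate is selected when its
#' median CV kappa strictly exceeds the upper confidence limit of the
#' baseline kappa. The candidate's tetrachoric correlation with the target
#' is reported alongside.
#'
#' @param data a normalized [survey_dataset()].
#' @param target target species name.
#' @param baseline the [train_baseline()] model.
#' @param candidates candidate species (must exclude the target); defaults
#'   to all non-target species.
#' @param config a [train_config()].
#' @param folds,seed,cutoff_mode as in [cross_validate()].
#' @return An object of class `screening_result`: `baseline` (list `k`,
#'   `ci_low`, `ci_high`), `candidates` (data frame `species`, `r`,
#'   `median_kappa`, `selected`), and `cv` (per-candidate reports).
#' @export
screen_copredictors <- function(data, target, baseline,
                                candidates = setdiff(data$species_names,
                                                     target),
                                config = train_config(),
                                folds = 5, seed = 1,
                                cutoff_mode = c("test", "train")) {
  cutoff_mode <- match.arg(cutoff_mode)
  validate_survey(data)
  if (target %in% candidates) {
    stop("candidates must not include the target species", call. = FALSE)
  }
  unknown <- setdiff(candidates, data$species_names)
  if (length(unknown)) {
    stop("unknown candidate species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base_ci <- attr(baseline, "baseline_ci")
  base_k <- attr(baseline, "baseline_k")
  if (is.null(base_ci)) {
    base_k <- cohen_kappa(baseline$cv$median_fold_matrix)$k
    base_ci <- kappa_ci(baseline$cv$median_fold_matrix)
  }
  yt <- data$occurrence[, target]
  cvs <- list()
  rows <- lapply(seq_along(candidates), function(i) {
    sp <- candidates[i]
    r <- tryCatch(
      tetrachoric_r(contingency_from_binary(yt, data$occurrence[, sp]))$r,
      error = function(e) NA_real_)
    cv <- cross_validate(data, target,
                         species_net_factory(config, extra_inputs = sp),
                         k = folds, seed = derive_seed(seed, i),
                         cutoff_mode = cutoff_mode)
    cvs[[sp]] <<- cv
    data.frame(species = sp, r = r, median_kappa = cv$median_k,
               selected = cv$median_k > base_ci[["high"]])
  })
  cand_df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(species = character(0), r = numeric(0),
               median_kappa = numeric(0), selected = logical(0))
  }
  cand_df <- cand_df[order(-cand_df$median_kappa), , drop = FALSE]
  rownames(cand_df) <- NULL
  structure(list(baseline = list(k = base_k,
                                 ci_low = base_ci[["low"]],
                                 ci_high = base_ci[["high"]]),
                 candidates = cand_df,
                 cv = cvs),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening vs baseline k = %.3f (CI %.3f-%.3f):\n",
              x$baseline$k, x$baseline$ci_low, x$baseline$ci_high))
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Step 3: environment-only sub-model for a co-predictor species
#'
#' Identical in form to the baseline model but aimed at the co-predictor:
#' the sub-model's predicted occurrence probability later replaces the
#' species' observed occurrence in the cascade.
#'
#' @param data a normalized [survey_dataset()].
#' @param copredictor co-predictor species name.
#' @param config,folds,seed,cutoff_mode as in [train_baseline()].
#' @return A `model_spec` for the co-predictor with its own ROC cutoff and
#'   CV report.
#' @export
train_submodel <- function(data, copredictor, config = train_config(),
                           folds = 5, seed = 1,
                           cutoff_mode = c("test", "train")) {
  train_baseline(data, copredictor, config = config, folds = folds,
                 seed = seed, cutoff_mode = match.arg(cutoff_mode))
}

# Out-of-fold sub-model occurrence probabilities for every site: the
# probability for each site comes from a network trained without that site's
# fold, avoiding optimistic leakage into cascade training.
oof_submodel_probs <- function(data, species, config, folds, seed) {
  fold <- stratified_folds(data, species, k = folds,
                           seed = derive_seed(seed, 811))
  probs <- numeric(length(fold))
  for (i in seq_len(folds)) {
    tr <- subset_sites(data, fold != i)
    cfg <- config
    cfg$seed <- derive_seed(seed, 811 + i)
    w <- train_network(tr$environment, tr$occurrence[, species], cfg)
    probs[fold == i] <- nn_forward(w, data$environment[fold == i, ,
                                                       drop = FALSE])
  }
  probs
}

#' Step 4: assemble the cascaded model
#'
#' Combines the target model with the environment-only sub-models so that
#' biotic inputs are supplied by sub-model predictions at run time. In the
#' default `"retrain"` composition a new target network is trained on the
#' environmental variables plus the sub-model occurrence probabilities
#' (computed out-of-fold for the training sites unless `oof = FALSE`); in
#' the `"reuse"` composition the screening-stage network trained on observed
#' occurrences is kept unchanged and simply fed sub-model probabilities.
#'
#' @param data a normalized [survey_dataset()].
#' @param target target species name.
#' @param selected co-predictor species feeding the cascade (may be empty,
#'   in which case the cascade degenerates to the environment-only model).
#' @param sub_models named list of [train_submodel()] results covering
#'   exactly the selected species.
#' @param config a [train_config()].
#' @param folds,seed,cutoff_mode as in [cross_validate()].
#' @param composition `"retrain"` (default) or `"reuse"`.
#' @param oof use out-of-fold sub-model probabilities during training
#'   (default TRUE).
#' @param binarize_inputs feed 0/1 sub-model calls (at each sub-model's
#'   cutoff) instead of continuous probabilities (default FALSE).
#' @param step2_model required for `"reuse"`: the screening-stage
#'   `model_spec` trained with the selected species' observed occurrences.
#' @param cv cross-validate the assembled cascade end-to-end (default TRUE;
#'   sub-models are refit within each training fold, so this is the honest
#'   generalization estimate but also the expensive part).
#' @return An object of class `cascade_model`: `target_model` (a
#'   `model_spec` whose species inputs are in `predicted_probability` mode)
#'   and `sub_models`.
#' @export
assemble_cascade <- function(data, target, selected, sub_models,
                             config = train_config(), folds = 5, seed = 1,
                             cutoff_mode = c("test", "train"),
                             composition = c("retrain", "reuse"),
                             oof = TRUE, binarize_inputs = FALSE,
                             step2_model = NULL, cv = TRUE) {
  cutoff_mode <- match.arg(cutoff_mode)
  composition <- match.arg(composition)
  validate_survey(data)
  missing_sub <- setdiff(selected, names(sub_models))
  if (length(missing_sub)) {
    stop("missing sub-model for: ", paste(missing_sub, collapse = ", "),
         call. = FALSE)
  }
  extra_sub <- setdiff(names(sub_models), selected)
  if (length(extra_sub)) {
    stop("sub-model supplied for non-selected species: ",
         paste(extra_sub, collapse = ", "), call. = FALSE)
  }
  sub_models <- sub_models[selected]

  cv_report <- NULL
  if (cv && length(selected) > 0) {
    cv_report <- cross_validate(
      data, target,
      cascade_factory(selected, config, folds = folds, oof = oof,
                      composition = composition,
                      binarize_inputs = binarize_inputs,
                      sub_cutoffs = vapply(sub_models, `[[`, numeric(1),
                                           "cutoff")),
      k = folds, seed = seed, cutoff_mode = cutoff_mode)
  }

  if (length(selected) == 0) {
    target_model <- fit_final_model(data, target, character(0), config,
                                    seed = derive_seed(seed, 0),
                                    cv = cv_report)
    return(structure(list(target_model = target_model,
                          sub_models = list(),
                          composition = composition,
                          binarize_inputs = binarize_inputs,
                          norm_params = data$norm_params),
                     class = "cascade_model"))
  }

  feats <- sapply(seq_along(selected), function(i) {
    sp <- selected[i]
    pr <- if (oof) {
      oof_submodel_probs(data, sp, config, folds,
                         seed = derive_seed(seed, 100 + i))
    } else {
      nn_forward(sub_models[[sp]]$weights, data$environment)
    }
    if (binarize_inputs) pr <- binarize(pr, sub_models[[sp]]$cutoff)
    pr
  })
  feats <- matrix(feats, ncol = length(selected),
                  dimnames = list(NULL, selected))

  if (composition == "retrain") {
    cfg <- config
    cfg$seed <- derive_seed(seed, 0)
    x <- cbind(data$environment, feats)
    y <- data$occurrence[, target]
    w <- train_network(x, y, cfg)
    cutoff <- roc_analysis(nn_forward(w, x), y)$best_cutoff
    target_model <- model_spec(target = target,
                               input_env = data$env_names,
                               input_species = selected,
                               input_mode = "predicted_probability",
                               weights = w, cutoff = cutoff,
                               cv = cv_report, config = cfg)
  } else {
    if (is.null(step2_model)) {
      stop("composition = 'reuse' requires the step-2 model trained with ",
           "observed co-predictor occurrences (step2_model)", call. = FALSE)
    }
    if (!identical(sort(step2_model$input_species), sort(selected))) {
      stop("step2_model species inputs do not match the selection",
           call. = FALSE)
    }
    target_model <- step2_model
    target_model$input_mode <- "predicted_probability"
    target_model$cv <- cv_report %||% target_model$cv
  }

  structure(list(target_model = target_model,
                 sub_models = sub_models,
                 composition = composition,
                 binarize_inputs = binarize_inputs,
                 norm_params = data$norm_params),
            class = "cascade_model")
}

# Factory evaluating the whole cascade pipeline inside each CV training
# fold: sub-models are refit on the training data only.
cascade_factory <- function(selected, config, folds = 5, oof = TRUE,
                            composition = "retrain",
                            binarize_inputs = FALSE, sub_cutoffs = NULL) {
  force(selected); force(config)
  function(train_data, target, seed) {
    sub_w <- lapply(seq_along(selected), function(i) {
      cfg <- config
      cfg$seed <- derive_seed(seed, 200 + i)
      train_network(train_data$environment,
                    train_data$occurrence[, selected[i]], cfg)
    })
    names(sub_w) <- selected
    cuts <- if (binarize_inputs) {
      vapply(seq_along(selected), function(i) {
        if (!is.null(sub_cutoffs)) sub_cutoffs[[i]] else {
          roc_analysis(nn_forward(sub_w[[i]], train_data$environment),
                       train_data$occurrence[, selected[i]])$best_cutoff
        }
      }, numeric(1))
    } else NULL
    feats_tr <- sapply(seq_along(selected), function(i) {
      pr <- if (oof) {
        oof_submodel_probs(train_data, selected[i], config, folds,
                           seed = derive_seed(seed, 300 + i))
      } else {
        nn_forward(sub_w[[i]], train_data$environment)
      }
      if (binarize_inputs) pr <- binarize(pr, cuts[i])
      pr
    })
    feats_tr <- matrix(feats_tr, ncol = length(selected))
    x_inputs <- if (composition == "retrain") {
      cbind(train_data$environment, feats_tr)
    } else {
      model_inputs(train_data, selected)  # observed occurrences, step-2 style
    }
    cfg <- config
    cfg$seed <- as.integer(seed)
    w <- train_network(x_inputs, train_data$occurrence[, target], cfg)
    list(weights = w,
         predict = function(newdata) {
           fnew <- sapply(seq_along(selected), function(i) {
             pr <- nn_forward(sub_w[[i]], newdata$environment)
             if (binarize_inputs) pr <- binarize(pr, cuts[i])
             pr
           })
           fnew <- matrix(fnew, ncol = length(selected))
           nn_forward(w, cbind(newdata$environment, fnew))
         })
  }
}

#' Predict from a cascaded model using environmental data only
#'
#' Sub-model occurrence probabilities are computed first from the
#' environmental columns (matched by name), appended to the target network's
#' inputs, and the target probability binarized at the stored cutoff. No
#' species column is ever read, so predictions are identical whether or not
#' community data accompany the input.
#'
#' @param model a [assemble_cascade()] result.
#' @param newdata a [survey_dataset()], data frame, or matrix providing the
#'   model's environmental columns (extra columns are ignored; order is
#'   irrelevant).
#' @param normalize `"auto"` (default): rescale the input with the
#'   normalization parameters stored in the model when `newdata` is an
#'   unnormalized [survey_dataset()]; matrices and data frames are assumed
#'   to be on the model's training scale already. `TRUE` forces rescaling
#'   (raw field values in, requires stored parameters), `FALSE` disables
#'   it.
#' @return A data frame with the target's `probability` and binary
#'   `prediction`, plus `<species>_probability` / `<species>_prediction`
#'   columns for each sub-model.
#' @export
predict_cascade <- function(model, newdata, normalize = "auto") {
  stopifnot(inherits(model, "cascade_model"))
  env_names <- model$target_model$input_env
  env <- if (inherits(newdata, "survey_dataset")) {
    newdata$environment
  } else {
    as.matrix(as.data.frame(newdata))
  }
  missing_cols <- setdiff(env_names, colnames(env))
  if (length(missing_cols)) {
    stop("missing environmental column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  env <- env[, env_names, drop = FALSE]
  storage.mode(env) <- "double"
  if (identical(normalize, "auto")) {
    normalize <- inherits(newdata, "survey_dataset") && !newdata$normalized
  }
  if (isTRUE(normalize)) {
    if (is.null(model$norm_params)) {
      stop("model carries no normalization parameters; supply inputs on ",
           "the training scale", call. = FALSE)
    }
    i <- match(env_names, model$norm_params$variable)
    mins <- model$norm_params$min[i]
    maxs <- model$norm_params$max[i]
    env <- sweep(sweep(env, 2, mins, `-`), 2, maxs - mins, `/`)
    env <- pmin(pmax(env, 0), 1)
  }
  out <- data.frame(row.names = seq_len(nrow(env)))
  feats <- NULL
  for (sp in model$target_model$input_species) {
    sm <- model$sub_models[[sp]]
    pr <- nn_forward(sm$weights, env)
    out[[paste0(sp, "_probability")]] <- pr
    out[[paste0(sp, "_prediction")]] <- binarize(pr, sm$cutoff)
    if (model$binarize_inputs) pr <- binarize(pr, sm$cutoff)
    feats <- cbind(feats, pr)
  }
  x <- if (is.null(feats)) env else cbind(env, feats)
  p <- nn_forward(model$target_model$weights, x)
  out$probability <- p
  out$prediction <- binarize(p, model$target_model$cutoff)
  out
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("cascade_model for '", x$target_model$target, "' (",
      x$composition, " composition)\n", sep = "")
  cat("  sub-models:",
      if (length(x$sub_models)) paste(names(x$sub_models), collapse = ", ")
      else "none (environment-only)", "\n")
  if (!is.null(x$target_model$cv)) {
    cat("  cascade CV median kappa =",
        sprintf("%.3f", x$target_model$cv$median_k), "\n")
  }
  invisible(x)
}
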