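# End-to-end orchestration: preprocess -> correlate -> baseline -> screen
# -> sub-models -> cascade -> sensitivity, with every artefact written to
# an output directory and a structured run log. The command-line script in
# inst/scripts/ is a thin wrapper over these functions.

log_stage <- function(log_path, stage, seed, t0, extra = list()) {
  rec <- c(list(stage = stage, seed = seed,
                elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
           extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the four-step cascade workflow end to end
#'
#' Normalizes the environment (global min-max, unless already normalized),
#' ranks candidate species by tetrachoric correlation with the target,
#' trains the environment-only baseline, screens every candidate as an
#' observed-occurrence co-predictor, trains sub-models for the selected
#' species, assembles the cascade and runs the three importance methods on
#' it. All tabular outputs are CSV, the model bundle JSON; a JSON-lines run
#' log records stages, seeds and timings.
#'
#' @param data a [survey_dataset()] (raw or normalized).
#' @param target target species name.
#' @param out_dir output directory (created if needed).
#' @param candidates candidate co-predictors (default all other species).
#' @param config a [train_config()].
#' @param folds,seed,cutoff_mode as in [cross_validate()].
#' @param min_presences rare-species threshold applied before modelling.
#' @param exclude species names dropped regardless of rarity.
#' @param sens_config a [sensitivity_config()].
#' @param cv_cascade cross-validate the assembled cascade (default TRUE).
#' @return Invisibly, a list with the normalized data, screening result,
#'   cascade model, and output paths.
#' @export
run_cascade_workflow <- function(data, target, out_dir,
                                 candidates = NULL,
                                 config = train_config(n_hidden = 5,
                                                       weight_decay = 0.003,
                                                       restarts = 3,
                                                       max_iterations = 300),
                                 folds = 5, seed = 1,
                                 cutoff_mode = c("test", "train"),
                                 min_presences = 10,
                                 exclude = character(0),
                                 sens_config = sensitivity_config(),
                                 cv_cascade = TRUE) {
  cutoff_mode <- match.arg(cutoff_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  t0 <- as.numeric(Sys.time())

  if (length(exclude)) {
    ex <- exclude_species(data, exclude)
    data <- ex$data
    write_exclusion_report(ex$report,
                           file.path(out_dir, "excluded_listed.json"))
  }
  fr <- filter_rare_species(data, min_presences = min_presences)
  data <- fr$data
  write_exclusion_report(fr$report,
                         file.path(out_dir, "excluded_rare.json"))
  if (!target %in% data$species_names) {
    stop("preprocess: target species '", target,
         "' was removed by filtering", call. = FALSE)
  }
  if (!data$normalized) data <- normalize_environment(data)
  log_stage(log_path, "preprocess", seed, t0,
            list(n_sites = length(data$site_ids),
                 n_species = length(data$species_names)))

  if (is.null(candidates)) {
    candidates <- setdiff(data$species_names, target)
  }
  ranking <- correlation_ranking(data, target)
  utils::write.csv(ranking, file.path(out_dir, "correlation_ranking.csv"),
                   row.names = FALSE)
  log_stage(log_path, "correlate", seed, t0)

  baseline <- train_baseline(data, target, config = config, folds = folds,
                             seed = derive_seed(seed, 1),
                             cutoff_mode = cutoff_mode)
  write_cv_report(baseline$cv, file.path(out_dir, "baseline_cv.csv"))
  log_stage(log_path, "baseline", derive_seed(seed, 1), t0,
            list(median_kappa = baseline$cv$median_k))

  screening <- screen_copredictors(data, target, baseline,
                                   candidates = candidates,
                                   config = config, folds = folds,
                                   seed = derive_seed(seed, 2),
                                   cutoff_mode = cutoff_mode)
  utils::write.csv(screening$candidates,
                   file.path(out_dir, "screening.csv"), row.names = FALSE)
  selected <- screening$candidates$species[screening$candidates$selected]
  log_stage(log_path, "screen", derive_seed(seed, 2), t0,
            list(selected = selected))

  sub_models <- list()
  for (i in seq_along(selected)) {
    sp <- selected[i]
    sub_models[[sp]] <- train_submodel(data, sp, config = config,
                                       folds = folds,
                                       seed = derive_seed(seed, 10 + i),
                                       cutoff_mode = cutoff_mode)
    write_cv_report(sub_models[[sp]]$cv,
                    file.path(out_dir, paste0("submodel_", sp, "_cv.csv")))
  }
  log_stage(log_path, "submodels", seed, t0)

  cascade <- assemble_cascade(data, target, selected, sub_models,
                              config = config, folds = folds,
                              seed = derive_seed(seed, 3),
                              cutoff_mode = cutoff_mode, cv = cv_cascade)
  save_cascade(cascade, file.path(out_dir, "cascade_model.json"))
  if (!is.null(cascade$target_model$cv)) {
    write_cv_report(cascade$target_model$cv,
                    file.path(out_dir, "cascade_cv.csv"))
  }
  log_stage(log_path, "cascade", derive_seed(seed, 3), t0,
            list(median_kappa = cascade$target_model$cv$median_k %||% NA))

  utils::write.csv(olden_weights(cascade),
                   file.path(out_dir, "importance_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(perturbation_importance(cascade, data, sens_config),
                   file.path(out_dir, "importance_perturbation.csv"),
                   row.names = FALSE)
  utils::write.csv(lek_profile(cascade, data, sens_config),
                   file.path(out_dir, "lek_profiles.csv"),
                   row.names = FALSE)
  log_stage(log_path, "sensitivity", sens_config$seed, t0)

  invisible(list(data = data, ranking = ranking, screening = screening,
                 sub_models = sub_models, cascade = cascade,
                 out_dir = out_dir))
}
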