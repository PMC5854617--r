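# JSON persistence for trained networks and cascade bundles. Weights are
# written at full double precision so a save/load round trip is exact.

weights_to_list <- function(w) {
  list(n_inputs = w$n_inputs, n_hidden = w$n_hidden,
       input_to_hidden = as.numeric(w$input_to_hidden),
       hidden_to_output = w$hidden_to_output)
}

weights_from_list <- function(l) {
  network_weights(matrix(l$input_to_hidden, l$n_inputs + 1L, l$n_hidden),
                  l$hidden_to_output)
}

spec_to_list <- function(ms) {
  list(target = ms$target,
       input_env = as.list(ms$input_env),
       input_species = as.list(ms$input_species),
       input_mode = ms$input_mode,
       cutoff = ms$cutoff,
       weights = weights_to_list(ms$weights),
       config = ms$config[c("n_hidden", "loss", "weight_decay",
                            "max_iterations", "tolerance", "init_range",
                            "restarts", "seed")])
}

spec_from_list <- function(l) {
  cfg <- do.call(train_config, l$config)
  model_spec(target = l$target,
             input_env = unlist(l$input_env) %||% character(0),
             input_species = unlist(l$input_species) %||% character(0),
             input_mode = l$input_mode,
             weights = weights_from_list(l$weights),
             cutoff = l$cutoff, cv = NULL, config = cfg)
}

#' Save a cascade model as a JSON bundle
#'
#' All networks, cutoffs, variable name lists and a configuration echo are
#' written in one JSON document at full precision. Cross-validation reports
#' are not persisted (export them with [write_cv_report()]).
#'
#' @param model a [assemble_cascade()] result.
#' @param path output path.
#' @return `model`, invisibly.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  bundle <- list(
    format = "cascadeSDM/cascade",
    version = 1L,
    composition = model$composition,
    binarize_inputs = model$binarize_inputs,
    norm_params = model$norm_params,
    target_model = spec_to_list(model$target_model),
    sub_models = lapply(model$sub_models, spec_to_list))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(model)
}

#' Load a cascade model from a JSON bundle
#'
#' @param path path written by [save_cascade()].
#' @return A `cascade_model`.
#' @export
load_cascade <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!identical(b$format, "cascadeSDM/cascade")) {
    stop("not a cascade bundle: ", path, call. = FALSE)
  }
  subs <- lapply(b$sub_models, spec_from_list)
  np <- b$norm_params
  if (!is.null(np)) {
    np <- data.frame(variable = unlist(lapply(np, `[[`, "variable")),
                     min = unlist(lapply(np, `[[`, "min")),
                     max = unlist(lapply(np, `[[`, "max")))
  }
  structure(list(target_model = spec_from_list(b$target_model),
                 sub_models = subs,
                 composition = b$composition,
                 binarize_inputs = isTRUE(b$binarize_inputs),
                 norm_params = np),
            class = "cascade_model")
}

#' Export an exclusion report as JSON
#'
#' @param report an exclusion report from [filter_rare_species()] or
#'   [exclude_species()].
#' @param path output path.
#' @return `report`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(
    list(removed_rare = report$removed_rare,
         removed_listed = report$removed_listed,
         retained = report$retained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
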