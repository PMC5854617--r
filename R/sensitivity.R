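# Variable importance for trained networks: Lek response profiles, input
# perturbation, and the connection-weights (input->hidden->output product)
# method.

#' Sensitivity analysis configuration
#'
#' @param profile_scale number of evenly spaced sweep points per variable in
#'   the Lek profile (default 50).
#' @param profile_levels `"quartiles"`: other variables held at their
#'   minimum, Q1, median, Q3 and maximum observed values; `"fixed_grid"`:
#'   held at 0, 0.25, 0.5, 0.75, 1.
#' @param noise_range half-width of the symmetric uniform perturbation noise
#'   (default 0.3, i.e. noise on \[-0.3, 0.3\]).
#' @param noise_reps number of seeded noise repetitions to average (default
#'   100).
#' @param clip clip perturbed values back to the normalized \[0, 1\] domain
#'   (default TRUE).
#' @param seed integer seed for the noise draws.
#' @return An object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(profile_scale = 50,
                               profile_levels = c("quartiles", "fixed_grid"),
                               noise_range = 0.3,
                               noise_reps = 100,
                               clip = TRUE,
                               seed = 1) {
  profile_levels <- match.arg(profile_levels)
  stopifnot(profile_scale >= 2, noise_range >= 0, noise_reps >= 0)
  structure(list(profile_scale = as.integer(profile_scale),
                 profile_levels = profile_levels,
                 noise_range = noise_range,
                 noise_reps = as.integer(noise_reps),
                 clip = isTRUE(clip),
                 seed = as.integer(seed)),
            class = "sensitivity_config")
}

# Resolve any supported model into (network weights, input matrix over the
# network's input space, input names, observed target). Cascade sub-model
# probability inputs are materialized like any other variable, so importance
# methods treat them exactly as the environmental inputs.
sensitivity_context <- function(model, data) {
  if (inherits(model, "network_weights")) {
    stop("supply a model_spec or cascade_model so input columns can be ",
         "resolved by name", call. = FALSE)
  }
  if (inherits(model, "cascade_model")) {
    tm <- model$target_model
    env <- data$environment[, tm$input_env, drop = FALSE]
    feats <- sapply(tm$input_species, function(sp) {
      pr <- nn_forward(model$sub_models[[sp]]$weights, env)
      if (model$binarize_inputs) {
        pr <- binarize(pr, model$sub_models[[sp]]$cutoff)
      }
      pr
    })
    x <- if (length(tm$input_species)) {
      cbind(env, matrix(feats, ncol = length(tm$input_species)))
    } else env
    colnames(x) <- c(tm$input_env, tm$input_species)
    list(weights = tm$weights, x = x,
         names = c(tm$input_env, tm$input_species), target = tm$target)
  } else if (inherits(model, "model_spec")) {
    x <- model_inputs(data, model$input_species)
    colnames(x) <- c(model$input_env, model$input_species)
    list(weights = model$weights, x = x,
         names = c(model$input_env, model$input_species),
         target = model$target)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
}

#' Lek response profiles
#'
#' Each input variable in turn sweeps `profile_scale` evenly spaced points
#' over \[0, 1\] while all other inputs are held at one of five reference
#' levels, yielding five response curves of the network output per
#' variable. In `"quartiles"` mode the levels are each variable's observed
#' minimum, first quartile, median, third quartile and maximum; in
#' `"fixed_grid"` mode they are 0, 0.25, 0.5, 0.75 and 1.
#'
#' @param model a `model_spec` or `cascade_model`.
#' @param data a normalized [survey_dataset()] supplying the reference
#'   distribution.
#' @param config a [sensitivity_config()].
#' @return Long-format data frame: `variable`, `level` (min/Q1/median/Q3/max
#'   or the grid value), `x`, `response`.
#' @export
lek_profile <- function(model, data, config = sensitivity_config()) {
  ctx <- sensitivity_context(model, data)
  grid <- seq(0, 1, length.out = config$profile_scale)
  level_names <- c("min", "Q1", "median", "Q3", "max")
  out <- list()
  for (j in seq_along(ctx$names)) {
    for (l in 1:5) {
      base <- if (config$profile_levels == "quartiles") {
        apply(ctx$x, 2, function(col) {
          stats::quantile(col, probs = c(0, 0.25, 0.5, 0.75, 1),
                          names = FALSE)[l]
        })
      } else {
        rep(c(0, 0.25, 0.5, 0.75, 1)[l], ncol(ctx$x))
      }
      sweep_x <- matrix(rep(base, each = length(grid)),
                        nrow = length(grid))
      sweep_x[, j] <- grid
      out[[length(out) + 1L]] <- data.frame(
        variable = ctx$names[j],
        level = if (config$profile_levels == "quartiles") level_names[l]
                else sprintf("%.2f", c(0, 0.25, 0.5, 0.75, 1)[l]),
        x = grid,
        response = nn_forward(ctx$weights, sweep_x))
    }
  }
  do.call(rbind, out)
}

#' Perturbation importance
#'
#' Uniform white noise on `[-noise_range, noise_range]` is added to one
#' input variable at a time (all others untouched; perturbed values clipped
#' back to \[0, 1\] by default), and the model's mean squared error against
#' the observed target occurrence is recomputed. Importance is the percent
#' increase of MSE over the unperturbed baseline, averaged over
#' `noise_reps` seeded repetitions.
#'
#' @param model a `model_spec` or `cascade_model`.
#' @param data a normalized [survey_dataset()] including the target column.
#' @param config a [sensitivity_config()].
#' @param against `"observations"` (default): MSE measured against observed
#'   occurrence; `"predictions"`: mean squared difference from the
#'   unperturbed predictions, as a percentage of the baseline MSE.
#' @return Data frame `variable`, `mse_increase_pct`, `rank` (1 = most
#'   influential).
#' @export
perturbation_importance <- function(model, data,
                                    config = sensitivity_config(),
                                    against = c("observations",
                                                "predictions")) {
  against <- match.arg(against)
  if (config$noise_reps < 1) {
    stop("noise_reps must be at least 1", call. = FALSE)
  }
  ctx <- sensitivity_context(model, data)
  y <- data$occurrence[, ctx$target]
  p0 <- nn_forward(ctx$weights, ctx$x)
  mse0 <- mean((p0 - y)^2)
  n <- nrow(ctx$x)
  incr <- with_seed(config$seed, {
    vapply(seq_along(ctx$names), function(j) {
      deltas <- vapply(seq_len(config$noise_reps), function(r) {
        xp <- ctx$x
        xp[, j] <- xp[, j] + stats::runif(n, -config$noise_range,
                                          config$noise_range)
        if (config$clip) xp[, j] <- pmin(pmax(xp[, j], 0), 1)
        p <- nn_forward(ctx$weights, xp)
        if (against == "observations") {
          mean((p - y)^2) - mse0
        } else {
          mean((p - p0)^2)
        }
      }, numeric(1))
      100 * mean(deltas) / mse0
    }, numeric(1))
  })
  out <- data.frame(variable = ctx$names, mse_increase_pct = incr)
  out$rank <- rank(-out$mse_increase_pct, ties.method = "min")
  out
}

#' Connection-weights (Olden) importance
#'
#' Signed contribution of each input: the product of the input-to-hidden and
#' hidden-to-output connection weights summed across hidden neurons (bias
#' terms excluded). Positive contributions mean increasing values of the
#' input raise the predicted presence probability.
#'
#' @param weights a `network_weights`, `model_spec`, or `cascade_model`
#'   (the cascade's target network is used).
#' @return Data frame `variable`, `contribution`, `rank` (by absolute
#'   contribution).
#' @export
olden_weights <- function(weights) {
  nm <- NULL
  if (inherits(weights, "cascade_model")) {
    nm <- c(weights$target_model$input_env,
            weights$target_model$input_species)
    weights <- weights$target_model$weights
  } else if (inherits(weights, "model_spec")) {
    nm <- c(weights$input_env, weights$input_species)
    weights <- weights$weights
  }
  stopifnot(inherits(weights, "network_weights"))
  w_in <- weights$input_to_hidden[seq_len(weights$n_inputs), , drop = FALSE]
  v <- weights$hidden_to_output[seq_len(weights$n_hidden)]
  contrib <- as.numeric(w_in %*% v)
  out <- data.frame(
    variable = nm %||% paste0("input", seq_len(weights$n_inputs)),
    contribution = contrib)
  out$rank <- rank(-abs(out$contribution), ties.method = "min")
  out
}
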